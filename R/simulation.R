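# Monte Carlo simulation: item-quality profiles, generating item parameters,
# uniform attribute patterns, binary responses, and Q-matrix construction.

#' Item quality profile
#'
#' Item quality is defined by the guessing probability `g` (success of the
#' least capable latent group) and slip `s` (failure of the most capable
#' group, taken equal to `g` so that the most capable group succeeds with
#' probability `1 - g`).  High / moderate / low quality use intercepts
#' 0.05 / 0.10 / 0.15, mean main-effect sizes 0.16 / 0.15 / 0.13 and mean
#' interaction sizes 0.10 / 0.08 / 0.07.
#'
#' @param level `"high"`, `"moderate"` or `"low"`.
#' @return List with `intercept` (= `g`), `max_prob` (= `1 - s`),
#'   `main` (mean main-effect size) and `interaction` (mean interaction
#'   size).
#' @export
quality_profile <- function(level = c("high", "moderate", "low")) {
  level <- match.arg(level)
  prof <- switch(level,
    high     = list(intercept = 0.05, main = 0.16, interaction = 0.10),
    moderate = list(intercept = 0.10, main = 0.15, interaction = 0.08),
    low      = list(intercept = 0.15, main = 0.13, interaction = 0.07))
  prof$max_prob <- 1 - prof$intercept
  prof$level <- level
  stopifnot(prof$intercept < prof$max_prob)
  prof
}

#' Generate item parameters under a quality profile
#'
#' Deterministic scheme: the intercept is set to `g`; every main-effect
#' column gets the profile's mean main-effect size and every interaction
#' column the mean interaction size (for the two-parameter conjunctive and
#' disjunctive models, the single effect is `1 - s - g` directly).  All
#' non-intercept effects are then rescaled by a common factor so that the
#' most capable latent group's success probability is exactly `1 - s`.
#' The resulting probabilities are monotone (all effects are non-negative
#' under cumulative step coding) and lie in `[g, 1 - s]`.
#'
#' @param q_row Q-matrix row.
#' @param spec An [attribute_spec()] object.
#' @param model_kind Generating model kind.
#' @param profile A [quality_profile()].
#' @param link Link function of the generating model (effects are assigned
#'   on the probability scale and mapped through the link for the saturated
#'   model; reduced generating models use the identity link).
#' @return A parameterized [item_model()].
#' @export
generate_item_parameters <- function(q_row, spec, model_kind = "saturated",
                                     profile = quality_profile("high"),
                                     link = "identity") {
  im <- item_model(model_kind, q_row, spec, link = link)
  ord <- attr(im$design, "order")
  raw <- numeric(ncol(im$design))
  raw[ord == 0L] <- 0          # intercept handled on probability scale
  raw[ord == 1L] <- profile$main
  raw[ord > 1L] <- profile$interaction
  g <- profile$intercept; top <- profile$max_prob
  if (top <= g) stop("infeasible quality profile: 1 - s <= g")
  # probability-scale construction, then map through the link
  incr <- drop(im$design %*% raw) - raw[1L]   # intercept column is 1s
  maxinc <- max(incr)
  p <- g + incr * (top - g) / maxinc
  eta <- .linkfun(p, im$link)
  delta <- if (ncol(im$design) == nrow(im$design))
    drop(solve(im$design, eta)) else drop(qr.solve(im$design, eta))
  # reduced designs reproduce eta exactly because incr lives in their span
  im$delta <- delta
  stopifnot(max(abs(.linkinv(drop(im$design %*% delta), im$link) - p)) < 1e-8)
  im
}

#' Generate attribute patterns uniformly over the latent classes
#'
#' @param N Number of examinees.
#' @param spec An [attribute_spec()] object.
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return `N x K` integer pattern matrix with attribute `"class"` giving
#'   the class index of each examinee.
#' @export
generate_attributes <- function(N, spec, seed = NULL) {
  .assert_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  cls <- sample.int(spec$n_classes, N, replace = TRUE)
  patterns <- enumerate_patterns(spec)[cls, , drop = FALSE]
  attr(patterns, "class_index") <- cls
  patterns
}

#' Generate binary responses from item models
#'
#' `x_ij ~ Bernoulli(P_j(class_i))`.
#'
#' @param patterns Pattern matrix from [generate_attributes()] (or any
#'   `N x K` level matrix).
#' @param item_models List of parameterized [item_model()]s.
#' @param spec An [attribute_spec()] object.
#' @param seed Optional integer seed.
#' @return `N x J` binary matrix.
#' @export
generate_responses <- function(patterns, item_models, spec, seed = NULL) {
  .assert_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  cls <- attr(patterns, "class_index")
  if (is.null(cls)) cls <- .encode_patterns(as.matrix(patterns), spec$levels)
  P <- class_success_matrix(item_models, spec)
  Pp <- P[cls, , drop = FALSE]
  X <- (matrix(stats::runif(length(Pp)), nrow(Pp)) < Pp) * 1L
  colnames(X) <- paste0("item", seq_len(ncol(X)))
  X
}

# One cycle of multi-attribute filler rows: all attribute pairs crossed with
# all required-level combinations, then attribute triples.
.filler_rows <- function(spec) {
  K <- spec$K
  rows <- list()
  if (K >= 2L) {
    for (pair in utils::combn(K, 2L, simplify = FALSE)) {
      grid <- .step_grid(spec$levels[pair])
      for (r in seq_len(nrow(grid))) {
        q <- integer(K); q[pair] <- grid[r, ]
        rows[[length(rows) + 1L]] <- q
      }
    }
  }
  if (K >= 3L) {
    for (tri in utils::combn(K, 3L, simplify = FALSE)) {
      grid <- .step_grid(spec$levels[tri])
      for (r in seq_len(nrow(grid))) {
        q <- integer(K); q[tri] <- grid[r, ]
        rows[[length(rows) + 1L]] <- q
      }
    }
  }
  do.call(rbind, rows)
}

#' Construct a simulation Q-matrix
#'
#' The `balanced` template emits, for every attribute `k` and level
#' `m >= 1`, two single-attribute items requiring exactly level `m` (the
#' coverage sufficient-condition heuristic), then fills the remaining rows
#' with two- and three-attribute items cycling through level combinations.
#' A 52-item request duplicates the 26-item matrix row for row.
#'
#' @param K Number of attributes (used when `spec` is `NULL`; levels then
#'   default to 3 per attribute).
#' @param spec Optional [attribute_spec()].
#' @param J Number of items.
#' @param template `"balanced"` (procedural) or `"paper"` (requires a
#'   transcribed fixture file under `extdata`, not bundled).
#' @return `J x K` integer Q-matrix.
#' @export
make_qmatrix <- function(K = 3, spec = NULL, J = 26,
                         template = c("balanced", "paper")) {
  template <- match.arg(template)
  if (is.null(spec)) spec <- attribute_spec(rep(3L, K))
  .assert_spec(spec)
  K <- spec$K
  if (template == "paper") {
    f <- system.file("extdata", sprintf("qmatrix_K%d_J26.csv", K),
                     package = "spcdm")
    if (!nzchar(f) || !file.exists(f))
      stop("no transcribed Q-matrix fixture available for K = ", K,
           "; use template = 'balanced'")
    Q <- as.matrix(utils::read.csv(f))
    storage.mode(Q) <- "integer"
  } else {
    singles <- list()
    for (k in seq_len(K))
      for (m in seq_len(spec$levels[k] - 1L))
        for (dup in 1:2) {
          q <- integer(K); q[k] <- m
          singles[[length(singles) + 1L]] <- q
        }
    base <- do.call(rbind, singles)
    J_base <- if (J %% 26L == 0L) 26L else J
    fill <- .filler_rows(spec)
    while (nrow(base) < J_base)
      base <- rbind(base, fill[seq_len(min(nrow(fill),
                                           J_base - nrow(base))), ,
                               drop = FALSE])
    Q <- base[seq_len(J_base), , drop = FALSE]
    while (nrow(Q) < J) Q <- rbind(Q, Q[seq_len(min(nrow(Q), J - nrow(Q))), ,
                                        drop = FALSE])
    Q <- Q[seq_len(J), , drop = FALSE]
  }
  colnames(Q) <- paste0("A", seq_len(K))
  rownames(Q) <- NULL
  Q
}

#' Simulate one complete dataset
#'
#' Convenience wrapper tying together [make_qmatrix()],
#' [generate_item_parameters()], [generate_attributes()] and
#' [generate_responses()].
#'
#' @param N Examinees.
#' @param spec An [attribute_spec()]; defaults to `K` three-level
#'   attributes.
#' @param K,J Q-matrix dimensions (used when `Q` is `NULL`).
#' @param Q Optional Q-matrix (overrides `K`/`J`).
#' @param quality Item quality level.
#' @param model_kind Generating model.
#' @param seed Integer seed for patterns and responses.
#' @return List with `Q`, `spec`, `item_models`, `truth` (per-item
#'   generating group probabilities), `patterns`, `responses`.
#' @export
simulate_spcdm <- function(N, spec = NULL, K = 3, J = 26, Q = NULL,
                           quality = "high", model_kind = "saturated",
                           seed = NULL) {
  if (is.null(spec)) spec <- attribute_spec(rep(3L, K))
  if (is.null(Q)) Q <- make_qmatrix(spec = spec, J = J)
  prof <- quality_profile(quality)
  ims <- lapply(seq_len(nrow(Q)), function(j)
    generate_item_parameters(Q[j, ], spec, model_kind, prof))
  if (!is.null(seed)) set.seed(seed)
  patterns <- generate_attributes(N, spec)
  X <- generate_responses(patterns, ims, spec)
  list(Q = Q, spec = spec, item_models = ims,
       truth = lapply(ims, group_probabilities),
       patterns = patterns, responses = X)
}
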