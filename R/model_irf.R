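# Item response functions: design matrices for the saturated model and its
# reduced special cases, group success probabilities under identity / logit /
# log links, and monotonicity diagnostics.

.LINKS <- c("identity", "logit", "log")

.linkfun <- function(p, link) {
  switch(link, identity = p, logit = stats::qlogis(p), log = log(p))
}

.linkinv <- function(eta, link) {
  switch(link, identity = eta, logit = stats::plogis(eta), log = exp(eta))
}

# Level-combination grid over chosen attributes (each m_k in 1..M_k-1),
# last attribute varying fastest; rows are combinations.
.step_grid <- function(M) {
  g <- expand.grid(lapply(rev(M), function(Mk) seq_len(Mk - 1L)),
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, rev(seq_along(M)), drop = FALSE])
}

#' Build the design matrix of an item model
#'
#' Maps an item's latent groups to linear-predictor rows.  All models use
#' cumulative step indicators `I(alpha_k >= m)`: the main effect of level
#' `m` of attribute `k` is the increment for reaching level `m` from
#' `m - 1`.  Columns are ordered intercept, then main effects (attribute-
#' major, level-minor), then interactions by increasing order and
#' lexicographically within order.
#'
#' Model kinds:
#' * `saturated`: one column per non-empty attribute subset and step-level
#'   combination plus the intercept; square and invertible, `prod(M_k)`
#'   columns over the required attributes.
#' * `pG-DINA`: dichotomous G-DINA design on the collapsed indicators
#'   `d_k = I(alpha_k >= q_jk)` (the specific-attribute-level-mastery
#'   assumption); `2^K*_j` columns.
#' * `fA-M`: intercept plus all main-effect step columns.
#' * `min-fA-M` / `max-fA-M`: intercept plus step columns with
#'   `m >= q_jk` / `m <= q_jk` only.
#' * `conjunctive` / `disjunctive`: intercept plus a single indicator that
#'   all / at least one required attribute is at or above its required
#'   level.
#'
#' @param model_kind Model kind (see [count_item_parameters()] for
#'   accepted names).
#' @param q_row Q-matrix row of the item.
#' @param spec An [attribute_spec()] object.
#' @param equal_steps If `TRUE`, merge each attribute's main-effect step
#'   columns into a single column (their sum), constraining all steps
#'   within an attribute to share one effect.  Applies to the models with
#'   main-effect step columns (saturated main-effect block, fA-M family).
#' @return Numeric matrix with one row per latent group (ordering of
#'   [partition_groups()]) and attribute `"order"` giving each column's
#'   interaction order (0 = intercept, 1 = main effect, ...).
#' @examples
#' sp <- attribute_spec(3)
#' build_design_matrix("saturated", 1, sp)   # lower-triangular 3 x 3
#' @export
build_design_matrix <- function(model_kind, q_row, spec, equal_steps = FALSE) {
  kind <- .canon_kind(model_kind)
  pg <- partition_groups(q_row, spec)
  A <- pg$groups                      # G x K* group level matrix
  M <- spec$levels[pg$required]
  qs <- pg$q_req
  G <- nrow(A)
  Kr <- ncol(A)

  step_block <- function(keep = NULL) {
    # main-effect step columns I(alpha_k >= m); keep[[k]] selects m values
    cols <- list(); nms <- character(0); ord <- integer(0)
    for (k in seq_len(Kr)) {
      ms <- if (is.null(keep)) seq_len(M[k] - 1L) else keep[[k]]
      for (m in ms) {
        cols[[length(cols) + 1L]] <- as.numeric(A[, k] >= m)
        nms <- c(nms, sprintf("A%d>=%d", pg$required[k], m))
        ord <- c(ord, 1L)
      }
    }
    list(cols = cols, nms = nms, ord = ord)
  }

  intercept <- list(cols = list(rep(1, G)), nms = "(Intercept)", ord = 0L)

  built <- switch(kind,
    saturated = {
      cols <- intercept$cols; nms <- intercept$nms; ord <- intercept$ord
      for (s in seq_len(Kr)) {
        subsets <- utils::combn(Kr, s, simplify = FALSE)
        for (S in subsets) {
          grid <- .step_grid(M[S])
          for (r in seq_len(nrow(grid))) {
            col <- rep(1, G)
            for (t in seq_along(S))
              col <- col * (A[, S[t]] >= grid[r, t])
            cols[[length(cols) + 1L]] <- col
            nms <- c(nms, paste(sprintf("A%d>=%d", pg$required[S], grid[r, ]),
                                collapse = ":"))
            ord <- c(ord, s)
          }
        }
      }
      list(cols = cols, nms = nms, ord = ord)
    },
    pgdina = {
      D <- matrix(as.numeric(t(t(A) >= qs)), G, Kr)
      cols <- intercept$cols; nms <- intercept$nms; ord <- intercept$ord
      for (s in seq_len(Kr)) {
        subsets <- utils::combn(Kr, s, simplify = FALSE)
        for (S in subsets) {
          cols[[length(cols) + 1L]] <-
            apply(D[, S, drop = FALSE], 1L, prod)
          nms <- c(nms, paste(sprintf("d%d", pg$required[S]), collapse = ":"))
          ord <- c(ord, s)
        }
      }
      list(cols = cols, nms = nms, ord = ord)
    },
    fam = {
      b <- step_block()
      list(cols = c(intercept$cols, b$cols), nms = c(intercept$nms, b$nms),
           ord = c(intercept$ord, b$ord))
    },
    minfam = {
      b <- step_block(lapply(seq_len(Kr), function(k) seq(qs[k], M[k] - 1L)))
      list(cols = c(intercept$cols, b$cols), nms = c(intercept$nms, b$nms),
           ord = c(intercept$ord, b$ord))
    },
    maxfam = {
      b <- step_block(lapply(seq_len(Kr), function(k) seq_len(qs[k])))
      list(cols = c(intercept$cols, b$cols), nms = c(intercept$nms, b$nms),
           ord = c(intercept$ord, b$ord))
    },
    conj = {
      col <- as.numeric(rowSums(t(t(A) >= qs)) == Kr)
      list(cols = c(intercept$cols, list(col)),
           nms = c(intercept$nms, "all-at-required"), ord = c(0L, 1L))
    },
    disj = {
      col <- as.numeric(rowSums(t(t(A) >= qs)) > 0)
      list(cols = c(intercept$cols, list(col)),
           nms = c(intercept$nms, "any-at-required"), ord = c(0L, 1L))
    })

  D <- do.call(cbind, built$cols)
  colnames(D) <- built$nms
  ord <- built$ord

  if (equal_steps && kind %in% c("saturated", "fam", "minfam", "maxfam")) {
    newD <- D[, ord == 0L, drop = FALSE]
    neword <- ord[ord == 0L]
    for (k in seq_len(Kr)) {
      pat <- sprintf("^A%d>=", pg$required[k])
      sel <- ord == 1L & grepl(pat, colnames(D))
      if (any(sel)) {
        merged <- rowSums(D[, sel, drop = FALSE])
        newD <- cbind(newD, merged)
        colnames(newD)[ncol(newD)] <- sprintf("A%d(steps)", pg$required[k])
        neword <- c(neword, 1L)
      }
    }
    keep <- ord > 1L
    if (any(keep)) {
      newD <- cbind(newD, D[, keep, drop = FALSE])
      neword <- c(neword, ord[keep])
    }
    D <- newD; ord <- neword
  }

  if (qr(D)$rank < ncol(D))
    stop("internal error: rank-deficient design matrix for kind ", kind)
  if (kind == "saturated" && !equal_steps && ncol(D) != G)
    stop("internal error: saturated design is not square")
  attr(D, "order") <- ord
  D
}

#' Construct an item model
#'
#' Bundles an item's model kind, link function, latent-group partition,
#' design matrix and (optionally) parameter vector `delta`.
#'
#' @inheritParams build_design_matrix
#' @param link Link function: `"identity"`, `"logit"` or `"log"`.
#' @param delta Optional parameter vector (length = design columns).  The
#'   first element is the intercept; the rest are main-effect and
#'   interaction effects on the link scale.
#' @return Object of class `item_model`.
#' @export
item_model <- function(model_kind, q_row, spec,
                       link = c("identity", "logit", "log"),
                       delta = NULL, equal_steps = FALSE) {
  link <- match.arg(link)
  kind <- .canon_kind(model_kind)
  pg <- partition_groups(q_row, spec)
  D <- build_design_matrix(kind, q_row, spec, equal_steps = equal_steps)
  im <- structure(
    list(model_kind = kind, link = link, q_row = as.integer(q_row),
         partition = pg, design = D, delta = NULL,
         equal_steps = equal_steps),
    class = "item_model"
  )
  if (!is.null(delta)) {
    if (length(delta) != ncol(D))
      stop("delta must have length ", ncol(D))
    im$delta <- as.numeric(delta)
    group_probabilities(im)  # validates [0, 1]
  }
  im
}

#' @export
print.item_model <- function(x, ...) {
  cat("Item model:", x$model_kind, "(", x$link, "link ),",
      x$partition$n_groups, "latent groups,", ncol(x$design),
      "parameters\n")
  invisible(x)
}

#' Latent-group success probabilities of an item model
#'
#' Applies the inverse link to the linear predictor `D %*% delta`.  Under
#' the identity and log links the result can leave `[0, 1]` for invalid
#' parameter values; anything beyond `tol` is an error (probabilities are
#' never silently clipped).
#'
#' @param im An [item_model()].
#' @param delta Parameter vector; defaults to the one stored in `im`.
#' @param tol Absolute tolerance for the probability bounds.
#' @return Numeric vector of success probabilities, one per latent group.
#' @export
group_probabilities <- function(im, delta = im$delta, tol = 1e-8) {
  if (is.null(delta)) stop("item model has no parameter vector")
  eta <- drop(im$design %*% delta)
  p <- .linkinv(eta, im$link)
  if (any(p < -tol) || any(p > 1 + tol))
    stop("invalid parameters: success probabilities outside [0, 1]")
  pmin(pmax(p, 0), 1)
}

#' Expand item models to a class-by-item success probability matrix
#'
#' Every latent class inherits the success probability of its latent group,
#' producing the `C x J` matrix used by the marginal likelihood.
#'
#' @param item_models List of [item_model()] objects with parameters.
#' @param spec An [attribute_spec()] object.
#' @return Numeric matrix, `n_classes` rows, one column per item.
#' @export
class_success_matrix <- function(item_models, spec) {
  .assert_spec(spec)
  P <- vapply(item_models, function(im) {
    gp <- group_probabilities(im)
    gp[im$partition$group_index]
  }, numeric(spec$n_classes))
  matrix(P, nrow = spec$n_classes)
}

# Ordered pairs of latent groups differing by +1 level on exactly one
# required attribute (lo -> hi); monotone models must not decrease here.
.adjacent_group_pairs <- function(pg) {
  A <- pg$groups
  G <- nrow(A)
  lo <- integer(0); hi <- integer(0)
  key <- .encode_patterns(A, apply(A, 2, max) + 1L)
  lookup <- integer(max(key)); lookup[key] <- seq_len(G)
  lv <- apply(A, 2, max) + 1L
  w <- .pattern_weights(lv)
  for (g in seq_len(G)) {
    for (k in seq_len(ncol(A))) {
      if (A[g, k] + 1L < lv[k]) {
        hi_key <- key[g] + w[k]
        lo <- c(lo, g); hi <- c(hi, lookup[hi_key])
      }
    }
  }
  cbind(lo = lo, hi = hi)
}

#' Monotonicity violations of an item model
#'
#' Checks every ordered pair of latent groups that differ by one level on
#' exactly one required attribute and reports pairs where the success
#' probability decreases by more than `tol`.
#'
#' @param im An [item_model()] with parameters (or supply `probs`).
#' @param probs Optional probability vector to check instead of the model's.
#' @param tol Absolute tolerance.
#' @return Data frame with columns `lo`, `hi`, `p_lo`, `p_hi` (zero rows if
#'   the model is monotone).
#' @export
monotonicity_violations <- function(im, probs = NULL, tol = 1e-8) {
  p <- if (is.null(probs)) group_probabilities(im) else probs
  pairs <- .adjacent_group_pairs(im$partition)
  bad <- p[pairs[, "hi"]] < p[pairs[, "lo"]] - tol
  data.frame(lo = pairs[bad, "lo"], hi = pairs[bad, "hi"],
             p_lo = p[pairs[bad, "lo"]], p_hi = p[pairs[bad, "hi"]])
}
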