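# Marginal maximum likelihood estimation (EM), standard errors, examinee
# classification and fit statistics.

.PFLOOR <- 1e-10  # probability floor used inside likelihoods only

.floor_p <- function(p) pmin(pmax(p, .PFLOOR), 1 - .PFLOOR)

# N x C matrix of per-class log-likelihood contributions.
.class_loglik_matrix <- function(X, P) {
  Pf <- .floor_p(P)
  X %*% t(log(Pf)) + (1 - X) %*% t(log1p(-Pf))
}

.logsumexp_rows <- function(M) {
  m <- apply(M, 1L, max)
  m + log(rowSums(exp(M - m)))
}

.as_P_matrix <- function(item_models, spec = NULL) {
  if (is.matrix(item_models)) return(item_models)
  if (is.null(spec)) spec <- attr(item_models, "spec")
  class_success_matrix(item_models, spec)
}

#' Marginal log-likelihood of binary responses
#'
#' Computes `sum_i log sum_c pi_c prod_j P_jc^x (1 - P_jc)^(1 - x)` with a
#' log-sum-exp over classes.  Probabilities are floored at `1e-10` inside
#' the likelihood so deterministic items cannot produce `-Inf` spuriously.
#'
#' @param responses `N x J` binary matrix.
#' @param item_models List of parameterized [item_model()]s, or directly a
#'   `C x J` class success probability matrix.
#' @param pi Probability vector over the latent classes.
#' @param spec Attribute specification (needed when `item_models` is a
#'   list).
#' @return Log-likelihood (scalar).
#' @export
marginal_loglik <- function(responses, item_models, pi, spec = NULL) {
  X <- as.matrix(responses)
  P <- .as_P_matrix(item_models, spec)
  L <- .class_loglik_matrix(X, P)
  sum(.logsumexp_rows(sweep(L, 2L, log(pi), `+`)))
}

#' E-step: class posteriors and expected group counts
#'
#' @inheritParams marginal_loglik
#' @param item_models List of parameterized [item_model()]s.
#' @param P Optional precomputed `C x J` class success matrix (computed
#'   from `item_models` when omitted).
#' @return List with `posterior` (`N x C`, rows sum to 1), `loglik`, and
#'   `counts`: per item, `N_l` (expected examinees per latent group) and
#'   `R_l` (expected correct responses per latent group).
#' @export
e_step <- function(responses, item_models, pi, spec = NULL, P = NULL) {
  X <- as.matrix(responses)
  if (is.null(P)) P <- .as_P_matrix(item_models, spec)
  L <- sweep(.class_loglik_matrix(X, P), 2L, log(pi), `+`)
  ll_i <- .logsumexp_rows(L)
  post <- exp(L - ll_i)
  Nc <- colSums(post)                 # expected examinees per class
  Rc <- crossprod(post, X)            # C x J expected correct per class
  counts <- lapply(seq_along(item_models), function(j) {
    g <- item_models[[j]]$partition$group_index
    ng <- item_models[[j]]$partition$n_groups
    list(N_l = as.numeric(rowsum(Nc, g, reorder = TRUE)),
         R_l = as.numeric(rowsum(Rc[, j], g, reorder = TRUE)))
  })
  list(posterior = post, loglik = sum(ll_i), counts = counts)
}

# Weighted complete-data Bernoulli log-likelihood of one item.
.q_item <- function(p, N_l, R_l) {
  pf <- .floor_p(p)
  sum(R_l * log(pf) + (N_l - R_l) * log1p(-pf))
}

# Monotone projection by weighted adjacent-violator pooling over the
# latent-group partial order.  Feasible (monotone) on exit; each merge
# reduces the number of blocks so the loop terminates.
.isotone_pool <- function(p, w, pairs) {
  if (nrow(pairs) == 0L) return(p)
  block <- seq_along(p)
  repeat {
    v <- tapply(p * pmax(w, 1e-12), block, sum) /
      tapply(pmax(w, 1e-12), block, sum)
    val <- as.numeric(v[as.character(block)])
    viol <- which(block[pairs[, "lo"]] != block[pairs[, "hi"]] &
                  val[pairs[, "lo"]] > val[pairs[, "hi"]] + 1e-12)
    if (length(viol) == 0L) return(val)
    i <- viol[1L]
    b_lo <- block[pairs[i, "lo"]]; b_hi <- block[pairs[i, "hi"]]
    block[block == b_hi] <- b_lo
    p <- val
  }
}

#' M-step for a saturated item
#'
#' The unconstrained complete-data maximizer is `R_l / N_l`.  Groups with
#' expected size below `min_n` keep their previous value.  With
#' `monotone = TRUE` violations of the latent-group partial order are
#' removed by weighted adjacent-violator pooling; the update is accepted
#' only if it does not decrease the complete-data likelihood (generalized
#' EM), so the marginal log-likelihood never decreases.
#'
#' @param counts List with `N_l` and `R_l` (see [e_step()]).
#' @param im The item's [item_model()].
#' @param prev Previous group probability vector.
#' @param monotone Impose monotonicity over the group partial order?
#' @param min_n Expected-count threshold below which a group keeps its
#'   previous value.
#' @return Updated group probability vector.
#' @export
m_step_saturated <- function(counts, im, prev = NULL, monotone = FALSE,
                             min_n = 1e-3) {
  N_l <- counts$N_l; R_l <- counts$R_l
  p <- ifelse(N_l > min_n, R_l / pmax(N_l, .PFLOOR),
              if (is.null(prev)) 0.5 else prev)
  p <- pmin(pmax(p, 0), 1)
  if (monotone) {
    pairs <- .adjacent_group_pairs(im$partition)
    bad <- p[pairs[, "hi"]] < p[pairs[, "lo"]] - 1e-12
    if (any(bad)) p <- .isotone_pool(p, N_l, pairs)
  }
  if (!is.null(prev) && .q_item(p, N_l, R_l) < .q_item(prev, N_l, R_l))
    return(prev)
  p
}

#' M-step for a reduced (design-matrix) item model
#'
#' Maximizes the weighted complete-data Bernoulli likelihood in `delta`
#' with `p = linkinv(D delta)`, by quasi-Newton optimization with quadratic
#' penalties keeping probabilities inside `[eps, 1 - eps]` and (optionally)
#' enforcing monotonicity over the group partial order.  The update is
#' accepted only if it improves the complete-data likelihood; on optimizer
#' failure the previous iterate is kept.
#'
#' @inheritParams m_step_saturated
#' @param prev_delta Previous parameter vector (warm start).
#' @param eps Probability bound for the box penalty.
#' @param maxit Inner optimizer iteration cap.
#' @return Updated `delta`.
#' @export
m_step_reduced <- function(counts, im, prev_delta, monotone = FALSE,
                           eps = 1e-4, maxit = 50L) {
  D <- im$design; link <- im$link
  N_l <- counts$N_l; R_l <- counts$R_l
  pairs <- if (monotone) .adjacent_group_pairs(im$partition) else
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("lo", "hi")))
  lambda <- 1e6
  obj <- function(delta) {
    p <- .linkinv(drop(D %*% delta), link)
    pen <- sum(pmax(0, eps - p)^2) + sum(pmax(0, p - (1 - eps))^2)
    if (nrow(pairs))
      pen <- pen + sum(pmax(0, p[pairs[, "lo"]] - p[pairs[, "hi"]])^2)
    -(.q_item(p, N_l, R_l)) + lambda * pen
  }
  res <- tryCatch(
    stats::optim(prev_delta, obj, method = "BFGS",
                 control = list(maxit = maxit)),
    error = function(e) NULL)
  if (is.null(res)) {
    warning("M-step optimizer failed; keeping previous parameters")
    return(prev_delta)
  }
  cand <- res$par
  p_new <- .linkinv(drop(D %*% cand), link)
  p_old <- .linkinv(drop(D %*% prev_delta), link)
  feasible <- all(p_new > -1e-8 & p_new < 1 + 1e-8) &&
    (!nrow(pairs) ||
       all(p_new[pairs[, "hi"]] >= p_new[pairs[, "lo"]] - 1e-6))
  if (!feasible || .q_item(p_new, N_l, R_l) < .q_item(p_old, N_l, R_l))
    return(prev_delta)
  cand
}

#' Update the structural (latent class proportion) parameters
#'
#' Saturated multinomial maximizer: the mean posterior per class.
#'
#' @param posterior `N x C` posterior matrix.
#' @return Probability vector over classes.
#' @export
update_structural <- function(posterior) {
  pi <- colMeans(posterior)
  pi / sum(pi)
}

.default_fit_options <- function() {
  list(tol_p = 1e-4, tol_ll = 1e-7, max_iter = 2000L, monotone = TRUE,
       fix_pi_uniform = FALSE, init_seed = 17L, init_probs = NULL,
       init_pi = NULL, verbose = FALSE)
}

# Initial group probabilities: linear spacing over the monotone group order
# (by total level), plus small seeded perturbation to break symmetry.
.init_group_probs <- function(im) {
  G <- im$partition$n_groups
  ord <- order(rowSums(im$partition$groups), seq_len(G))
  p <- numeric(G)
  p[ord] <- seq(0.2, 0.8, length.out = G)
  p <- p + stats::runif(G, -0.05, 0.05)
  pmin(pmax(p, 0.05), 0.95)
}

# Map target group probabilities to a delta for a reduced model by least
# squares on the link scale; falls back to intercept-only if infeasible.
.init_delta <- function(im, p_target) {
  eta <- .linkfun(pmin(pmax(p_target, 0.05), 0.95), im$link)
  delta <- tryCatch(qr.solve(im$design, eta), error = function(e) NULL)
  ok <- !is.null(delta) && {
    p <- .linkinv(drop(im$design %*% delta), im$link)
    all(p > 1e-6 & p < 1 - 1e-6)
  }
  if (!ok) {
    delta <- numeric(ncol(im$design))
    delta[1L] <- .linkfun(mean(p_target), im$link)
  }
  delta
}

#' Fit a polytomous cognitive diagnosis model by MMLE/EM
#'
#' Alternates an E-step over the latent classes with per-item M-steps
#' (closed form for saturated items, design-matrix optimization for reduced
#' models) and a structural update of the class proportions, until the
#' maximum absolute change in any group success probability is below
#' `tol_p` and the relative log-likelihood change is below `tol_ll`, or
#' `max_iter` is reached.  Every M-step is ascent-guarded, so the marginal
#' log-likelihood trace is non-decreasing.
#'
#' @param responses `N x J` binary response matrix.
#' @param Q `J x K` integer Q-matrix (entries `0, ..., M_k - 1`; 0 = not
#'   required).
#' @param spec An [attribute_spec()] object.
#' @param model Model kind, length 1 or `J` (per item).
#' @param link Link function, length 1 or `J`.
#' @param options List overriding the defaults: `tol_p` (1e-4), `tol_ll`
#'   (1e-7), `max_iter` (2000), `monotone` (TRUE), `fix_pi_uniform`
#'   (FALSE), `init_seed` (17), `init_probs` / `init_pi` (warm starts,
#'   e.g. a previous fit's `group_probs` and `pi`), `verbose` (FALSE).
#' @param equal_steps Constrain steps within each attribute to be equal?
#' @return Object of class `spcdm_fit`: item models with estimates,
#'   `group_probs`, `pi`, `posterior`, `loglik`, `trace`, `converged`,
#'   `n_iter`, `counts` (final expected group counts), and metadata.
#' @examples
#' sp <- attribute_spec(c(2, 2))
#' Q <- rbind(c(1, 0), c(0, 1), c(1, 1))
#' ims <- lapply(1:3, function(j)
#'   item_model("saturated", Q[j, ], sp,
#'              delta = if (j < 3) c(0.1, 0.8) else c(0.1, 0.3, 0.3, 0.2)))
#' set.seed(1)
#' alpha <- generate_attributes(300, sp)
#' X <- generate_responses(alpha, ims, sp)
#' fit <- fit_em(X, Q, sp)
#' @export
fit_em <- function(responses, Q, spec, model = "saturated",
                   link = "identity", options = list(),
                   equal_steps = FALSE) {
  X <- as.matrix(responses)
  storage.mode(X) <- "double"
  if (any(is.na(X)) || !all(X %in% c(0, 1)))
    stop("responses must be a complete binary (0/1) matrix")
  Q <- as.matrix(Q)
  J <- nrow(Q)
  if (ncol(X) != J) stop("responses and Q-matrix disagree on item count")
  opt <- utils::modifyList(.default_fit_options(), options)
  model <- rep_len(model, J)
  link <- rep_len(link, J)

  ims <- lapply(seq_len(J), function(j)
    item_model(model[j], Q[j, ], spec, link = link[j],
               equal_steps = equal_steps))

  # seeded, RNG-state-preserving initialization (or warm start)
  if (!is.null(opt$init_probs)) {
    p_list <- lapply(opt$init_probs, function(p) pmin(pmax(p, 1e-6), 1 - 1e-6))
  } else {
    has_seed <- exists(".Random.seed", envir = globalenv())
    if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
    set.seed(opt$init_seed)
    p_list <- lapply(ims, .init_group_probs)
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }

  delta_list <- vector("list", J)
  saturated <- vapply(ims, function(im)
    im$model_kind == "saturated" && !im$equal_steps, logical(1))
  for (j in seq_len(J))
    if (!saturated[j]) {
      delta_list[[j]] <- .init_delta(ims[[j]], p_list[[j]])
      p_list[[j]] <- .linkinv(drop(ims[[j]]$design %*% delta_list[[j]]),
                              ims[[j]]$link)
    }

  C <- spec$n_classes
  pi <- if (!is.null(opt$init_pi)) opt$init_pi / sum(opt$init_pi) else
    rep(1 / C, C)
  gidx <- lapply(ims, function(im) im$partition$group_index)
  P <- vapply(seq_len(J), function(j) p_list[[j]][gidx[[j]]], numeric(C))

  trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  iter <- 0L
  counts <- NULL
  repeat {
    iter <- iter + 1L
    es <- e_step(X, ims, pi, spec = spec, P = P)
    counts <- es$counts
    ll <- es$loglik
    trace <- c(trace, ll)
    p_old <- p_list
    for (j in seq_len(J)) {
      if (saturated[j]) {
        p_list[[j]] <- m_step_saturated(counts[[j]], ims[[j]],
                                        prev = p_list[[j]],
                                        monotone = opt$monotone)
      } else {
        delta_list[[j]] <- m_step_reduced(counts[[j]], ims[[j]],
                                          prev_delta = delta_list[[j]],
                                          monotone = opt$monotone)
        p_list[[j]] <- .linkinv(drop(ims[[j]]$design %*% delta_list[[j]]),
                                ims[[j]]$link)
      }
    }
    if (!opt$fix_pi_uniform) pi <- update_structural(es$posterior)
    P <- vapply(seq_len(J), function(j) p_list[[j]][gidx[[j]]], numeric(C))
    max_dp <- max(vapply(seq_len(J), function(j)
      max(abs(p_list[[j]] - p_old[[j]])), numeric(1)))
    rel_dll <- if (is.finite(ll_prev))
      abs(ll - ll_prev) / max(abs(ll), 1) else Inf
    if (opt$verbose)
      message(sprintf("iter %d  loglik %.4f  max|dp| %.2e", iter, ll, max_dp))
    if (is.nan(ll)) stop("NaN marginal log-likelihood; aborting")
    if (max_dp < opt$tol_p && rel_dll < opt$tol_ll) { converged <- TRUE; break }
    if (iter >= opt$max_iter) break
    ll_prev <- ll
  }

  es <- e_step(X, ims, pi, spec = spec, P = P)
  for (j in seq_len(J)) {
    ims[[j]]$delta <- if (saturated[j])
      drop(solve(ims[[j]]$design,
                 .linkfun(.floor_p(p_list[[j]]), ims[[j]]$link)))
      else delta_list[[j]]
  }
  npar_item <- vapply(ims, function(im) ncol(im$design), integer(1))
  structure(
    list(item_models = ims, group_probs = p_list, pi = pi,
         posterior = es$posterior, loglik = es$loglik,
         trace = c(trace, es$loglik), converged = converged, n_iter = iter,
         counts = es$counts, spec = spec, Q = Q, responses = X,
         npar_item = npar_item, options = opt,
         model = model, link = link),
    class = "spcdm_fit"
  )
}

#' @export
print.spcdm_fit <- function(x, ...) {
  cat("Polytomous CDM fit (MMLE/EM)\n")
  cat("  items:", length(x$item_models),
      " examinees:", nrow(x$responses),
      " latent classes:", x$spec$n_classes, "\n")
  cat("  model:", paste(unique(x$model), collapse = "/"),
      " link:", paste(unique(x$link), collapse = "/"), "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Empirical cross-product standard errors
#'
#' Per-item standard errors from the inverse of the empirical cross-product
#' of per-examinee score vectors (incomplete-data scores via the posterior).
#' Saturated items are parameterized directly by their group success
#' probabilities; reduced models by `delta`.  Items whose information
#' matrix is singular (e.g. an empty latent group) are flagged unavailable
#' rather than given fabricated values.
#'
#' @param fit An [fit_em()] result.
#' @param responses Response matrix; defaults to the one stored in the fit.
#' @return List per item: `se` (vector, `NA` where unavailable),
#'   `available` (logical scalar), `parameterization` (`"probability"` or
#'   `"delta"`).
#' @export
standard_errors <- function(fit, responses = fit$responses) {
  X <- as.matrix(responses)
  post <- fit$posterior
  lapply(seq_along(fit$item_models), function(j) {
    im <- fit$item_models[[j]]
    g <- im$partition$group_index
    p_g <- fit$group_probs[[j]]
    pf <- .floor_p(p_g)
    # posterior mass per group for each examinee: N x G
    Wg <- t(rowsum(t(post), g, reorder = TRUE))  # N x G posterior mass
    resid <- outer(X[, j], pf, `-`)              # x_ij - p_l
    S_p <- Wg * resid / matrix(pf * (1 - pf), nrow(X), length(pf),
                               byrow = TRUE)
    if (im$model_kind == "saturated" && !im$equal_steps) {
      S <- S_p
      param <- "probability"
    } else {
      eta <- drop(im$design %*% im$delta)
      dmu <- switch(im$link, identity = rep(1, length(eta)),
                    logit = stats::plogis(eta) * (1 - stats::plogis(eta)),
                    log = exp(eta))
      S <- S_p %*% (im$design * dmu)
      param <- "delta"
    }
    info <- crossprod(S)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv) || any(!is.finite(diag(inv))) || any(diag(inv) < 0)) {
      list(se = rep(NA_real_, ncol(S)), available = FALSE,
           parameterization = param)
    } else {
      se <- sqrt(diag(inv))
      if (param == "probability") {
        empty <- fit$counts[[j]]$N_l < 1e-3
        se[empty] <- NA_real_
      }
      list(se = se, available = TRUE, parameterization = param)
    }
  })
}

#' Classify examinees from a fitted model
#'
#' MAP returns each examinee's highest-posterior latent class (ties broken
#' toward the lowest pattern index, for determinism); EAP returns marginal
#' posterior distributions per attribute, with the reported level the
#' marginal argmax.
#'
#' @param fit An [fit_em()] result.
#' @param method `"MAP"` or `"EAP"`.
#' @return For MAP, a list with `class` (indices) and `pattern` (`N x K`
#'   levels).  For EAP, additionally `marginals`: per attribute an
#'   `N x M_k` matrix of posterior level probabilities.
#' @export
classify <- function(fit, method = c("MAP", "EAP")) {
  method <- match.arg(method)
  post <- fit$posterior
  patterns <- enumerate_patterns(fit$spec)
  if (method == "MAP") {
    cls <- max.col(post, ties.method = "first")
    return(list(method = "MAP", class = cls,
                pattern = patterns[cls, , drop = FALSE]))
  }
  marg <- lapply(seq_len(fit$spec$K), function(k) {
    m <- t(rowsum(t(post), patterns[, k], reorder = TRUE))
    colnames(m) <- 0:(fit$spec$levels[k] - 1L)
    m
  })
  lev <- vapply(marg, function(m) max.col(m, ties.method = "first") - 1L,
                integer(nrow(post)))
  lev <- matrix(lev, nrow = nrow(post))
  colnames(lev) <- paste0("A", seq_len(fit$spec$K))
  list(method = "EAP", marginals = marg, pattern = lev)
}

#' Deviance, AIC and BIC of a fitted model
#'
#' The parameter count is the sum of per-item design columns plus the
#' `C - 1` free latent class proportions (0 when the fit held the class
#' distribution fixed at uniform).
#'
#' @param fit An [fit_em()] result.
#' @return Data frame with `deviance`, `npar`, `npar_items`,
#'   `npar_structural`, `AIC`, `BIC`, `N`.
#' @export
fit_statistics <- function(fit) {
  N <- nrow(fit$responses)
  p_items <- sum(fit$npar_item)
  p_struct <- if (isTRUE(fit$options$fix_pi_uniform)) 0L else
    fit$spec$n_classes - 1L
  p <- p_items + p_struct
  dev <- -2 * fit$loglik
  data.frame(deviance = dev, npar = p, npar_items = p_items,
             npar_structural = p_struct,
             AIC = dev + 2 * p, BIC = dev + p * log(N), N = N)
}
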