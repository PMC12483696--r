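# Evaluation metrics for simulation studies and fitted-model comparisons:
# bias / RMSE of group success probabilities, attribute and vector
# classification rates, posterior-weighted RMSD between fitted models, and a
# study driver over a condition grid.

#' Bias and RMSE of estimated group success probabilities
#'
#' `estimates` is a list over replications; each element is a list over
#' items of group probability vectors.  `truth` is the per-item list of
#' generating probabilities.  Per item,
#' `bias_j = mean_l (Pbar_jl - P_jl)` with `Pbar` the across-replication
#' mean estimate.  Two RMSE conventions are provided:
#' * `"per_rep"`: `mean_l sqrt(mean_r (Phat_jlr - P_jl)^2)` — the
#'   across-replication root-mean-square estimation error (default);
#' * `"mean_estimate"`: `sqrt(mean_l (Pbar_jl - P_jl)^2)` — the root mean
#'   square of the replication-averaged error across an item's latent
#'   groups, the convention matching published recovery summaries whose
#'   RMSE shrinks with the number of replications.
#'
#' @param estimates List (replications) of lists (items) of numeric
#'   vectors.
#' @param truth List (items) of numeric vectors.
#' @param rmse_mode `"per_rep"` or `"mean_estimate"`.
#' @return Object of class `recovery_summary`: data frame with `item`,
#'   `bias`, `rmse`, plus attributes `mean_bias` and `mean_rmse` (means
#'   over items).
#' @export
bias_rmse <- function(estimates, truth,
                      rmse_mode = c("per_rep", "mean_estimate")) {
  rmse_mode <- match.arg(rmse_mode)
  R <- length(estimates)
  if (R < 1L) stop("need at least one replication")
  J <- length(truth)
  per_item <- lapply(seq_len(J), function(j) {
    tr <- truth[[j]]
    est <- vapply(estimates, function(rep) {
      if (length(rep[[j]]) != length(tr))
        stop("dimension mismatch for item ", j)
      rep[[j]]
    }, numeric(length(tr)))
    est <- matrix(est, nrow = length(tr))    # groups x reps
    pbar <- rowMeans(est)
    bias <- mean(pbar - tr)
    rmse <- if (rmse_mode == "per_rep")
      mean(sqrt(rowMeans((est - tr)^2)))
    else sqrt(mean((pbar - tr)^2))
    c(bias = bias, rmse = rmse)
  })
  out <- data.frame(item = seq_len(J),
                    bias = vapply(per_item, `[[`, numeric(1), "bias"),
                    rmse = vapply(per_item, `[[`, numeric(1), "rmse"))
  attr(out, "mean_bias") <- mean(out$bias)
  attr(out, "mean_rmse") <- mean(out$rmse)
  attr(out, "rmse_mode") <- rmse_mode
  class(out) <- c("recovery_summary", "data.frame")
  out
}

#' Proportion of correctly classified attributes and vectors
#'
#' `PCA_k` is the percentage of examinee-replications whose estimated level
#' of attribute `k` matches the generating level; `PCV` the percentage
#' whose whole attribute vector matches.
#'
#' @param estimated,truth `N x K` level matrices, or lists of such
#'   matrices (one per replication).
#' @return List with `pca` (named percentage vector), `pca_mean`, and
#'   `pcv` (percentage).
#' @export
pca_pcv <- function(estimated, truth) {
  if (!is.list(estimated)) estimated <- list(estimated)
  if (!is.list(truth)) truth <- list(truth)
  if (length(estimated) != length(truth))
    stop("replication counts differ")
  match_k <- NULL; match_all <- NULL
  for (r in seq_along(estimated)) {
    e <- as.matrix(estimated[[r]]); t0 <- as.matrix(truth[[r]])
    if (!all(dim(e) == dim(t0))) stop("dimension mismatch in replication ", r)
    eq <- e == t0
    match_k <- rbind(match_k, eq)
    match_all <- c(match_all, rowSums(eq) == ncol(eq))
  }
  pca <- 100 * colMeans(match_k)
  names(pca) <- paste0("A", seq_along(pca))
  list(pca = pca, pca_mean = mean(pca), pcv = 100 * mean(match_all))
}

#' Posterior-weighted RMSD between two fitted models
#'
#' For each item, the root mean squared difference between two models'
#' latent-group success probabilities, weighted by the latent-group
#' posterior mass of a reference fit (its expected group counts divided by
#' `N`):
#' `RMSD_j = sqrt(sum_l w_jl (P_j^m(l) - P_j^m'(l))^2)`.
#'
#' @param fit_a,fit_b Fits sharing the same Q-matrix and attribute
#'   specification.
#' @param reference Fit supplying the posterior group weights (typically
#'   the saturated fit).
#' @return Data frame with `item` and `rmsd`, plus attribute `mean_rmsd`
#'   (average over items).
#' @export
rmsd_pair <- function(fit_a, fit_b, reference = fit_a) {
  J <- length(fit_a$item_models)
  if (length(fit_b$item_models) != J || length(reference$item_models) != J)
    stop("fits have different numbers of items")
  N <- nrow(reference$responses)
  rmsd <- vapply(seq_len(J), function(j) {
    pa <- fit_a$group_probs[[j]]; pb <- fit_b$group_probs[[j]]
    if (length(pa) != length(pb))
      stop("mismatched latent-group structures for item ", j)
    w <- reference$counts[[j]]$N_l / N
    if (length(w) != length(pa))
      stop("reference group structure mismatch for item ", j)
    sqrt(sum(w * (pa - pb)^2))
  }, numeric(1))
  out <- data.frame(item = seq_len(J), rmsd = rmsd)
  attr(out, "mean_rmsd") <- mean(rmsd)
  out
}

# Deterministic per-replication seed derivation (documented splitting rule).
.child_seed <- function(root, cond, gen, rep) {
  as.integer((as.double(root) * 1009 + cond * 100003 + gen * 101 +
                rep * 7919) %% 2147483629) + 1L
}

#' Run a simulation study over a condition grid
#'
#' For every condition (rows of `conditions`: columns `K`, `J`, `N`,
#' `quality`), every generating model and every fitted model, simulates
#' `reps` datasets (uniform attribute patterns, quality-profile item
#' parameters), fits by [fit_em()], classifies by MAP, and records
#' classification accuracy and estimated group probabilities.  Covers the
#' true-model, under-fit (reduced model on saturated data) and over-fit
#' (saturated model on reduced data) cells.
#'
#' @param conditions Data frame with columns `K`, `J`, `N`, `quality`.
#' @param gen_models Character vector of generating model kinds.
#' @param fit_models Character vector of fitted model kinds.
#' @param reps Replications per condition and generating model.
#' @param seed Root seed; per-replication seeds are derived by a fixed
#'   splitting rule.
#' @param options Fit options passed to [fit_em()].
#' @param rmse_mode Passed to [bias_rmse()].
#' @param keep_estimates Keep raw per-replication estimates?
#' @return Object of class `spcdm_study`: list with `per_rep` (one row per
#'   condition x generating model x fitted model x replication, with PCA,
#'   PCV, log-likelihood, convergence), `class_summary` (condition-level
#'   means), `recovery` (bias/RMSE per condition and model pair), and
#'   optionally `estimates`.
#' @export
run_study <- function(conditions, gen_models = "saturated",
                      fit_models = "saturated", reps = 25, seed = 1,
                      options = list(), rmse_mode = "per_rep",
                      keep_estimates = FALSE) {
  stopifnot(all(c("K", "J", "N", "quality") %in% names(conditions)))
  per_rep <- list(); recovery <- list(); estimates <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    spec <- attribute_spec(rep(3L, cond$K))
    Q <- make_qmatrix(spec = spec, J = cond$J)
    prof <- quality_profile(as.character(cond$quality))
    for (gi in seq_along(gen_models)) {
      gen <- gen_models[gi]
      ims <- lapply(seq_len(nrow(Q)), function(j)
        generate_item_parameters(Q[j, ], spec, gen, prof))
      truth <- lapply(ims, group_probabilities)
      est_by_fit <- stats::setNames(
        lapply(fit_models, function(f) vector("list", reps)), fit_models)
      for (r in seq_len(reps)) {
        set.seed(.child_seed(seed, ci, gi, r))
        patterns <- generate_attributes(cond$N, spec)
        X <- generate_responses(patterns, ims, spec)
        for (fm in fit_models) {
          fit <- tryCatch(
            fit_em(X, Q, spec, model = fm, options = options),
            error = function(e) e)
          if (inherits(fit, "error")) {
            per_rep[[length(per_rep) + 1L]] <- data.frame(
              condition = ci, K = cond$K, J = cond$J, N = cond$N,
              quality = as.character(cond$quality), gen = gen, fit = fm,
              rep = r, converged = NA, loglik = NA_real_,
              pca_mean = NA_real_, pcv = NA_real_,
              error = conditionMessage(fit))
            next
          }
          cl <- classify(fit, "MAP")
          acc <- pca_pcv(cl$pattern, patterns)
          row <- data.frame(
            condition = ci, K = cond$K, J = cond$J, N = cond$N,
            quality = as.character(cond$quality), gen = gen, fit = fm,
            rep = r, converged = fit$converged, loglik = fit$loglik,
            pca_mean = acc$pca_mean, pcv = acc$pcv, error = NA_character_)
          for (k in seq_along(acc$pca)) row[[paste0("pca", k)]] <- acc$pca[k]
          per_rep[[length(per_rep) + 1L]] <- row
          est_by_fit[[fm]][[r]] <- fit$group_probs
        }
      }
      for (fm in fit_models) {
        reps_ok <- Filter(Negate(is.null), est_by_fit[[fm]])
        if (length(reps_ok)) {
          rec <- bias_rmse(reps_ok, truth, rmse_mode = rmse_mode)
          recovery[[length(recovery) + 1L]] <- data.frame(
            condition = ci, K = cond$K, J = cond$J, N = cond$N,
            quality = as.character(cond$quality), gen = gen, fit = fm,
            reps = length(reps_ok),
            mean_bias = attr(rec, "mean_bias"),
            mean_rmse = attr(rec, "mean_rmse"))
        }
        if (keep_estimates)
          estimates[[paste(ci, gen, fm, sep = ".")]] <-
            list(truth = truth, estimates = est_by_fit[[fm]])
      }
    }
  }
  per_rep <- do.call(rbind, per_rep)
  agg_cols <- intersect(c("pca_mean", "pcv",
                          grep("^pca[0-9]+$", names(per_rep), value = TRUE)),
                        names(per_rep))
  class_summary <- stats::aggregate(
    per_rep[agg_cols],
    by = per_rep[c("condition", "K", "J", "N", "quality", "gen", "fit")],
    FUN = mean, na.rm = TRUE)
  structure(
    list(conditions = conditions, per_rep = per_rep,
         class_summary = class_summary,
         recovery = if (length(recovery)) do.call(rbind, recovery) else NULL,
         estimates = if (keep_estimates) estimates else NULL,
         seed = seed, reps = reps),
    class = "spcdm_study")
}

#' @export
print.spcdm_study <- function(x, ...) {
  cat("Simulation study:", nrow(x$conditions), "condition(s),",
      x$reps, "replication(s), seed", x$seed, "\n")
  print(x$class_summary, row.names = FALSE)
  invisible(x)
}
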