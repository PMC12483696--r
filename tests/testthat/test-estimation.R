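# MMLE/EM estimation: likelihood, E/M-steps, convergence behaviour,
# standard errors, classification and fit statistics.

test_that("marginal log-likelihood matches direct summation", {
  sp <- attribute_spec(c(2, 2))
  # 1 item, P = 0.5 everywhere: N * log(0.5) whatever the data
  P <- matrix(0.5, 4, 1)
  X <- matrix(c(0, 1, 1, 0, 1), ncol = 1)
  pi <- rep(0.25, 4)
  expect_equal(marginal_loglik(X, P, pi), 5 * log(0.5))

  # 2 classes, pi = (.5, .5), deterministic item, x = 1 -> log(.5)
  expect_equal(marginal_loglik(matrix(1, 1, 1), matrix(c(1, 0), 2, 1),
                               c(0.5, 0.5)),
               log(0.5), tolerance = 1e-7)

  # small random case vs brute-force summation oracle
  fx <- tiny_dichotomous(N = 40, seed = 3)
  P <- class_success_matrix(fx$item_models, fx$spec)
  pi <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(marginal_loglik(fx$responses, P, pi),
               brute_force_loglik(fx$responses, P, pi), tolerance = 1e-12)
})

test_that("E-step posteriors and expected counts behave correctly", {
  fx <- tiny_dichotomous(N = 60, seed = 5)
  # uniform pi and constant item probabilities -> uniform posteriors
  flat <- lapply(1:3, function(j)
    item_model("saturated", fx$Q[j, ], fx$spec,
               delta = if (j < 3) c(0.5, 0) else c(0.5, 0, 0, 0)))
  es0 <- e_step(fx$responses, flat, rep(0.25, 4), spec = fx$spec)
  expect_true(all(abs(es0$posterior - 0.25) < 1e-12))

  es <- e_step(fx$responses, fx$item_models, rep(0.25, 4), spec = fx$spec)
  expect_equal(unname(rowSums(es$posterior)), rep(1, 60))
  for (j in 1:3) {
    expect_equal(sum(es$counts[[j]]$N_l), 60)
    expect_true(all(es$counts[[j]]$R_l <= es$counts[[j]]$N_l + 1e-10))
    expect_true(all(es$counts[[j]]$R_l >= -1e-10))
  }

  # single deterministic item: posterior mass only on consistent classes
  sp1 <- attribute_spec(2)
  imd <- list(item_model("saturated", 1, sp1, delta = c(0, 1)))
  esd <- e_step(matrix(c(1, 0), 2, 1), imd, c(0.5, 0.5), spec = sp1)
  expect_equal(unname(esd$posterior[1, ]), c(0, 1), tolerance = 1e-8)
  expect_equal(unname(esd$posterior[2, ]), c(1, 0), tolerance = 1e-8)
})

test_that("saturated M-step is the weighted proportion with safeguards", {
  sp <- attribute_spec(2)
  im <- item_model("saturated", 1, sp)
  counts <- list(N_l = c(10, 20), R_l = c(1, 18))
  expect_equal(m_step_saturated(counts, im), c(0.1, 0.9))

  # R = N -> 1.0 reported (flooring happens only inside likelihoods)
  expect_equal(m_step_saturated(list(N_l = c(5, 5), R_l = c(0, 5)), im),
               c(0, 1))

  # empty group keeps its previous value
  expect_equal(
    m_step_saturated(list(N_l = c(1e-9, 10), R_l = c(0, 5)), im,
                     prev = c(0.33, 0.4)),
    c(0.33, 0.5))

  # ratio maximizes the weighted Bernoulli complete-data likelihood:
  # compare against a dense grid
  q_item <- function(p) sum(c(7, 30) * log(p) + (c(10, 40) - c(7, 30)) *
                              log(1 - p))
  grid <- as.matrix(expand.grid(seq(.01, .99, .01), seq(.01, .99, .01)))
  best <- grid[which.max(apply(grid, 1, function(r) q_item(r))), ]
  est <- m_step_saturated(list(N_l = c(10, 40), R_l = c(7, 30)), im)
  expect_equal(est, unname(best), tolerance = 0.011)
})

test_that("monotone M-step pools violating adjacent groups", {
  sp <- attribute_spec(3)
  im <- item_model("saturated", 1, sp)
  counts <- list(N_l = c(30, 10, 40), R_l = c(6, 9, 32))
  # unconstrained: (.2, .9, .8) violates between groups 2 and 3
  p <- m_step_saturated(counts, im, prev = c(0.2, 0.5, 0.8),
                        monotone = TRUE)
  expect_equal(nrow(monotonicity_violations(im, probs = p)), 0L)
  # pooled value is the weighted mean of the merged groups
  expect_equal(p, c(0.2, 41 / 50, 41 / 50))
})

test_that("reduced M-step reproduces closed forms", {
  sp <- attribute_spec(c(2, 2))
  # saturated design passed through the reduced path reproduces R/N
  im_s <- item_model("saturated", c(1, 1), sp)
  counts <- list(N_l = c(20, 10, 10, 25), R_l = c(2, 4, 5, 22))
  d0 <- c(0.3, 0.1, 0.1, 0.1)
  d <- m_step_reduced(counts, im_s, prev_delta = d0)
  expect_equal(drop(im_s$design %*% d), counts$R_l / counts$N_l,
               tolerance = 1e-4)

  # conjunctive: weighted means outside/inside the capable set
  im_c <- item_model("conjunctive", c(1, 1), sp)
  dc <- m_step_reduced(counts, im_c, prev_delta = c(0.3, 0.3))
  p_out <- sum(counts$R_l[1:3]) / sum(counts$N_l[1:3])
  p_in <- counts$R_l[4] / counts$N_l[4]
  expect_equal(dc[1], p_out, tolerance = 1e-4)
  expect_equal(dc[1] + dc[2], p_in, tolerance = 1e-4)

  # identity fA-M self-consistency: counts generated from an additive truth
  sp3 <- attribute_spec(c(3, 3))
  im_f <- item_model("fam", c(1, 2), sp3)
  delta_true <- c(0.1, 0.15, 0.1, 0.2, 0.25)
  p_true <- drop(im_f$design %*% delta_true)
  Nl <- rep(1000, 9)
  df <- m_step_reduced(list(N_l = Nl, R_l = Nl * p_true), im_f,
                       prev_delta = c(0.4, 0.05, 0.05, 0.05, 0.05))
  expect_equal(df, delta_true, tolerance = 1e-3)
})

test_that("structural update is the mean posterior", {
  post <- rbind(c(0, 0, 1, 0), c(0, 0, 1, 0))
  expect_equal(update_structural(post), c(0, 0, 1, 0))
  post2 <- matrix(0.25, 8, 4)
  expect_equal(update_structural(post2), rep(0.25, 4))
  set.seed(7)
  m <- matrix(runif(40), 10, 4)
  expect_equal(sum(update_structural(m / rowSums(m))), 1)
})

test_that("EM matches the identified moments and is a fixed point", {
  sp <- attribute_spec(c(2, 2))
  Q <- rbind(c(1, 0), c(0, 1))
  ims <- list(item_model("saturated", Q[1, ], sp, delta = c(0.4, 0)),
              item_model("saturated", Q[2, ], sp, delta = c(0.6, 0)))
  set.seed(11)
  pat <- generate_attributes(500, sp)
  X <- generate_responses(pat, ims, sp)
  fit <- fit_em(X, Q, sp, options = list(monotone = FALSE))
  # intercept-only truth leaves the group split unidentified (any split
  # with the same mixture margins fits equally well), but the fitted
  # marginal success rate is identified and must equal the item mean
  P <- class_success_matrix(fit$item_models, sp)
  for (j in 1:2)
    expect_equal(sum(fit$pi * P[, j]), mean(X[, j]), tolerance = 0.01)

  # refitting from the solution converges immediately
  fx <- tiny_dichotomous(N = 300, seed = 21)
  fit1 <- fit_em(fx$responses, fx$Q, fx$spec)
  fit2 <- fit_em(fx$responses, fx$Q, fx$spec,
                 options = list(init_probs = fit1$group_probs,
                                init_pi = fit1$pi))
  expect_lte(fit2$n_iter, 2L)
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-6)
})

test_that("EM log-likelihood trace is non-decreasing", {
  for (seed in c(2, 9)) {
    sim <- simulate_spcdm(300, K = 3, J = 12, quality = "moderate",
                          seed = seed)
    fit <- fit_em(sim$responses, sim$Q, sim$spec)
    expect_true(all(diff(fit$trace) >= -1e-8))
    fitm <- fit_em(sim$responses, sim$Q, sim$spec, model = "fam",
                   options = list(max_iter = 150))
    expect_true(all(diff(fitm$trace) >= -1e-8))
  }
})

test_that("EM attains the optimum of a dense grid-search oracle", {
  # two items, one dichotomous attribute, uniform classes held fixed:
  # the marginal likelihood depends only on the four response-pattern
  # counts, so a dense grid over the four item parameters is feasible
  sp <- attribute_spec(2)
  Q <- rbind(1, 1)
  ims <- list(item_model("saturated", 1, sp, delta = c(0.2, 0.6)),
              item_model("saturated", 1, sp, delta = c(0.3, 0.4)))
  set.seed(31)
  pat <- generate_attributes(200, sp)
  X <- generate_responses(pat, ims, sp)
  fit <- fit_em(X, Q, sp, options = list(fix_pi_uniform = TRUE,
                                         monotone = FALSE,
                                         tol_p = 1e-6, tol_ll = 1e-10))

  counts <- table(factor(X[, 1], 0:1), factor(X[, 2], 0:1))
  grid <- seq(0.02, 0.98, by = 0.03)
  gr <- as.matrix(expand.grid(p10 = grid, p11 = grid, p20 = grid,
                              p21 = grid))
  patlik <- function(g) {
    # P(x1, x2) = .5 * [ p1^x1 (1-p1)^(1-x1) p2^x2 (1-p2)^(1-x2) ]_class0
    #           + .5 * [ ... ]_class1
    ll <- 0
    for (x1 in 0:1) for (x2 in 0:1) {
      pr <- 0.5 * (g[, "p10"]^x1 * (1 - g[, "p10"])^(1 - x1) *
                     g[, "p20"]^x2 * (1 - g[, "p20"])^(1 - x2)) +
        0.5 * (g[, "p11"]^x1 * (1 - g[, "p11"])^(1 - x1) *
                 g[, "p21"]^x2 * (1 - g[, "p21"])^(1 - x2))
      ll <- ll + counts[x1 + 1, x2 + 1] * log(pr)
    }
    ll
  }
  best <- max(patlik(gr))
  expect_gte(fit$loglik, best - 1e-8)
})

test_that("standard errors match analytic limits", {
  # near-deterministic anchor items make the classification sharp, so the
  # probe item's group-probability SEs approach the per-group binomial
  # limit sqrt(p (1 - p) / N_l)
  sp <- attribute_spec(c(2, 2))
  Q <- rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1), c(0, 1), c(0, 1),
             c(1, 1))
  ims <- lapply(seq_len(6), function(j)
    item_model("saturated", Q[j, ], sp, delta = c(0.02, 0.96)))
  ims[[7]] <- item_model("saturated", Q[7, ], sp,
                         delta = c(0.15, 0.2, 0.25, 0.3))
  set.seed(41)
  pat <- generate_attributes(600, sp)
  X <- generate_responses(pat, ims, sp)
  fit <- fit_em(X, Q, sp, options = list(monotone = FALSE))
  se <- standard_errors(fit)
  j <- 1L
  p_g <- fit$group_probs[[j]]
  se_binom <- sqrt(p_g * (1 - p_g) / fit$counts[[j]]$N_l)
  expect_true(all(abs(se[[j]]$se / se_binom - 1) < 0.10))

  # duplicated dataset: SEs shrink by ~ 1/sqrt(2)
  X2 <- rbind(X, X)
  fit2 <- fit_em(X2, Q, sp, options = list(monotone = FALSE))
  se2 <- standard_errors(fit2)
  ratio <- se2[[7]]$se / se[[7]]$se
  expect_true(all(abs(ratio - 1 / sqrt(2)) < 0.08))

  # an empty latent group leaves that parameter flagged
  fit$counts[[7]]$N_l[4] <- 0
  se3 <- standard_errors(fit)
  expect_true(is.na(se3[[7]]$se[4]) || !se3[[7]]$available)
})

test_that("classification follows MAP/EAP rules and tie-breaks", {
  fx <- tiny_dichotomous(N = 50, seed = 51)
  fit <- fit_em(fx$responses, fx$Q, fx$spec)

  # MAP is the argmax class with ties to the lowest index
  fit_fake <- fit
  fit_fake$posterior <- rbind(c(0.6, 0.3, 0.1, 0.0),
                              c(0.5, 0.5, 0.0, 0.0))
  cl <- classify(fit_fake, "MAP")
  expect_equal(cl$class, c(1L, 1L))

  eap <- classify(fit, "EAP")
  for (k in 1:2)
    expect_equal(unname(rowSums(eap$marginals[[k]])), rep(1, 50),
                 tolerance = 1e-10)
  expect_true(all(eap$pattern %in% c(0L, 1L)))
})

test_that("fit statistics: nesting, parameter counts and identities", {
  sim <- simulate_spcdm(400, K = 3, J = 12, quality = "high", seed = 61)
  fit_sat <- fit_em(sim$responses, sim$Q, sim$spec)
  fit_fam <- fit_em(sim$responses, sim$Q, sim$spec, model = "fam",
                    options = list(max_iter = 200))
  fs_sat <- fit_statistics(fit_sat)
  fs_fam <- fit_statistics(fit_fam)

  expect_lte(fs_sat$deviance, fs_fam$deviance + 1e-6)
  expect_equal(fs_sat$AIC - fs_sat$deviance, 2 * fs_sat$npar)
  expect_equal(fs_sat$BIC - fs_sat$deviance, fs_sat$npar * log(400))
  expect_equal(fs_sat$npar_structural, 26L)
  expect_equal(fs_sat$npar_items,
               sum(vapply(seq_len(nrow(sim$Q)), function(j)
                 count_item_parameters("saturated", sim$Q[j, ], sim$spec),
                 integer(1))))
})
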