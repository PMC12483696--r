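# Shared fixture builders for the test suite.  Everything is generated in
# code; no data files.

# A tiny two-attribute dichotomous world with three items (two single-
# attribute, one two-attribute saturated item).
tiny_dichotomous <- function(N = 400, seed = 101) {
  sp <- attribute_spec(c(2, 2))
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1))
  ims <- list(
    item_model("saturated", Q[1, ], sp, delta = c(0.1, 0.8)),
    item_model("saturated", Q[2, ], sp, delta = c(0.15, 0.7)),
    item_model("saturated", Q[3, ], sp, delta = c(0.1, 0.2, 0.25, 0.35)))
  set.seed(seed)
  patterns <- generate_attributes(N, sp)
  X <- generate_responses(patterns, ims, sp)
  list(spec = sp, Q = Q, item_models = ims, patterns = patterns,
       responses = X)
}

# Direct (independent) marginal log-likelihood by brute-force summation
# over all latent classes, with no log-sum-exp and no shared code path.
brute_force_loglik <- function(X, P, pi) {
  N <- nrow(X)
  ll <- 0
  for (i in seq_len(N)) {
    mix <- 0
    for (c in seq_along(pi)) {
      lik <- 1
      for (j in seq_len(ncol(X)))
        lik <- lik * ifelse(X[i, j] == 1, P[c, j], 1 - P[c, j])
      mix <- mix + pi[c] * lik
    }
    ll <- ll + log(mix)
  }
  unname(ll)
}

# Cache for expensive shared computations within one test run.
.spcdm_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .spcdm_test_cache))
    assign(key, builder(), envir = .spcdm_test_cache)
  get(key, envir = .spcdm_test_cache)
}
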