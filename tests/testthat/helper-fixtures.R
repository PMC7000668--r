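# Shared fixtures and independent oracles for the test suite.

# small, fast MCMC protocol for unit tests (acceptance tests use their own)
quick_settings <- function(n_chains = 2, n_iter = 4000, thin = 2,
                           n_retain = 500, ...) {
  mcmc_settings(n_chains = n_chains, n_iter = n_iter, thin = thin,
                n_retain = n_retain, ...)
}

tiny_truth <- function(...) {
  args <- modifyList(list(intercept = -0.5, treatment = 1, openness = 0.02,
                          interaction = -0.04, slope = -0.05,
                          sigma_pair = 0.5, sigma_species = 0.5), list(...))
  do.call(true_parameters, args)
}

tiny_dataset <- function(seed = 1, n_pairs = 3, quadrats_per_plot = 2,
                         n_species = 5, truth = tiny_truth(),
                         layer = "seedbank") {
  des <- study_design(n_pairs = n_pairs,
                      quadrats_per_plot = quadrats_per_plot,
                      n_species = setNames(n_species, layer), layers = layer)
  q <- generate_design(des, seed)
  simulate_occurrence(q, truth, n_species, layer, seed = seed)
}

# Independent brute-force oracle for the unnormalized log posterior:
# explicit loops and stats densities, no shared code with the package.
oracle_logpost <- function(beta, u, v, r_pair, r_species, y, X,
                           pair_idx, sp_idx,
                           beta_var = 1e4, recip_upper = 1e9) {
  lp <- 0
  for (j in seq_along(beta)) lp <- lp + dnorm(beta[j], 0, sqrt(beta_var),
                                              log = TRUE)
  for (r in c(pair = r_pair, species = r_species)) {
    if (r <= 1 / recip_upper) return(-Inf)
    lp <- lp + log(1 / recip_upper) - 2 * log(r)
  }
  for (j in seq_along(u)) lp <- lp + dnorm(u[j], 0, sqrt(r_pair), log = TRUE)
  for (k in seq_along(v)) lp <- lp + dnorm(v[k], 0, sqrt(r_species),
                                           log = TRUE)
  if (length(y)) {
    for (i in seq_along(y)) {
      eta <- sum(X[i, ] * beta) + u[pair_idx[i]] + v[sp_idx[i]]
      lp <- lp + if (y[i] == 1) plogis(eta, log.p = TRUE) else
        plogis(-eta, log.p = TRUE)
    }
  }
  lp
}

# fixed five-observation toy model used by the log-posterior tests
toy_model <- function() {
  list(y = c(1L, 0L, 1L, 1L, 0L),
       X = cbind(intercept = 1,
                 treatment = c(1, 1, 0, 0, 1),
                 openness = c(20, 35, 50, 65, 42),
                 interaction = c(20, 35, 0, 0, 42),
                 slope = c(3, 10, 0, 25, 7)),
       pair_idx = c(1L, 1L, 2L, 2L, 1L),
       sp_idx = c(1L, 2L, 1L, 2L, 2L))
}

table1_seedbank_medians <- c(intercept = -3.4, treatment = 1.95,
                             openness = 0.01, interaction = -0.07,
                             slope = -0.061)
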