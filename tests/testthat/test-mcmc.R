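test_that("gelman_rubin matches the variance-ratio formula on small arrays", {
  # hand evaluation: W = mean chain variance, B/n = var of chain means,
  # PSRF = sqrt(((n-1)/n W + B/n) / W)
  x <- cbind(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             c(2, 4, 6, 8, 10, 1, 3, 5, 7, 9))
  W <- (var(x[, 1]) + var(x[, 2])) / 2
  B_over_n <- var(colMeans(x))
  expect_equal(gelman_rubin(x), sqrt((9 / 10 * W + B_over_n) / W),
               tolerance = 1e-12)

  # chains far apart relative to their spread must be flagged
  set.seed(60)
  apart <- cbind(rnorm(100, -10), rnorm(100, 10))
  expect_gt(gelman_rubin(apart), 5)

  # two long chains from the same distribution sit just above 1
  set.seed(61)
  same <- matrix(rnorm(20000), ncol = 2)
  expect_gte(gelman_rubin(same), 1 - 1e-9)
  expect_lt(gelman_rubin(same), 1.05)
})

test_that("gelman_rubin handles degenerate and invalid inputs", {
  expect_warning(psrf <- gelman_rubin(matrix(3, 20, 3)), "constant")
  expect_equal(psrf, 1)
  expect_equal(suppressWarnings(
    gelman_rubin(cbind(rep(1, 20), rep(2, 20)))), Inf)
  expect_error(gelman_rubin(matrix(rnorm(20), ncol = 1)), "2 chains")
  expect_error(gelman_rubin(matrix(rnorm(10), ncol = 2)), "10 draws")
})

test_that("run_mcmc is deterministic given the seed and records it", {
  d <- tiny_dataset(seed = 62)
  a <- build_design(d, "seedbank")
  s <- quick_settings(n_iter = 1200, n_retain = 200)
  f1 <- suppressWarnings(run_mcmc(a, settings = s, seed = 63))
  f2 <- suppressWarnings(run_mcmc(a, settings = s, seed = 63))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$seeds, f2$seeds)
  # identical chains give a unit scale-reduction factor
  expect_equal(gelman_rubin(cbind(f1$draws[f1$chain == 1, "treatment"],
                                  f2$draws[f2$chain == 1, "treatment"])),
               sqrt((nrow(f1$draws) / f1$settings$n_chains - 1) /
                      (nrow(f1$draws) / f1$settings$n_chains)),
               tolerance = 1e-10)
})

test_that("retained draws honour chains x retain and are all finite", {
  d <- tiny_dataset(seed = 64)
  a <- build_design(d, "seedbank")
  fit <- suppressWarnings(
    run_mcmc(a, settings = quick_settings(n_chains = 3, n_iter = 900,
                                          thin = 3, n_retain = 100),
             seed = 65))
  expect_equal(nrow(fit$draws), 300)
  expect_equal(fit$chain, rep(1:3, each = 100))
  expect_true(all(is.finite(fit$draws)))
  expect_true(all(fit$draws[, c("r_pair", "r_species")] > 0))
  # parameter layout: 5 betas + 3 pairs + 5 species + 2 variances
  expect_equal(ncol(fit$draws), 5 + 3 + 5 + 2)
})

test_that("a single chain is refused because diagnostics need two", {
  d <- tiny_dataset(seed = 66)
  a <- build_design(d, "seedbank")
  expect_error(run_mcmc(a, settings = quick_settings(n_chains = 1),
                        seed = 67), "2 chains")
})

test_that("with no observations the fixed effects sample their prior", {
  # the marginal posterior with an empty likelihood is Normal(0, 10,000);
  # heavy thinning gives near-independent draws for a distributional test
  arrays <- list(y = integer(0),
                 X = matrix(numeric(0), 0, 1,
                            dimnames = list(NULL, "intercept")))
  fit <- run_mcmc(arrays,
                  settings = mcmc_settings(n_chains = 2, n_iter = 60000,
                                           thin = 20, n_retain = 2000),
                  seed = 68)
  x <- fit$draws[, "intercept"]
  expect_gt(suppressWarnings(ks.test(x, "pnorm", 0, 100))$p.value, 0.01)
  expect_lt(abs(sd(x) - 100) / 100, 0.1)
})

test_that("MCMC agrees with dense-grid quadrature on a 2-parameter model", {
  # intercept + one slope, 30 observations: posterior means must match
  # quadrature of the same unnormalized posterior within Monte Carlo error
  set.seed(70)
  x <- runif(30, -2, 2)
  eta <- -0.3 + 0.9 * x
  y <- rbinom(30, 1, plogis(eta))
  arrays <- list(y = y, X = cbind(intercept = 1, slope_x = x))
  fit <- run_mcmc(arrays,
                  settings = mcmc_settings(n_chains = 2, n_iter = 20000,
                                           thin = 5, n_retain = 2000),
                  seed = 71)
  grid1 <- seq(-4, 4, length.out = 401)
  grid2 <- seq(-4, 6, length.out = 401)
  lp <- outer(grid1, grid2, Vectorize(function(b0, b1) {
    log_unnormalized_posterior(list(beta = c(b0, b1)), arrays)
  }))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mean_b0 <- sum(rowSums(w) * grid1)
  mean_b1 <- sum(colSums(w) * grid2)
  for (par in 1:2) {
    draws <- fit$draws[, par]
    want <- c(mean_b0, mean_b1)[par]
    expect_lt(abs(mean(draws) - want), 3 * mcse(draws) + 1e-3)
  }
})

test_that("relabelling the random-effect levels leaves the posterior alone", {
  d <- tiny_dataset(seed = 72, n_species = 4)
  # permute species labels (and matching rows); the model is exchangeable
  perm <- c("spZ", "spY", "spX", "spW")
  d2 <- d
  d2$occurrences$species_id <-
    perm[match(d2$occurrences$species_id, unique(d$occurrences$species_id))]
  a1 <- build_design(d, "seedbank")
  a2 <- build_design(d2, "seedbank")
  s <- quick_settings(n_iter = 6000, thin = 3, n_retain = 1000)
  f1 <- suppressWarnings(run_mcmc(a1, settings = s, seed = 73))
  f2 <- suppressWarnings(run_mcmc(a2, settings = s, seed = 73))
  for (b in f1$fixed_names) {
    tol <- 4 * (mcse(f1$draws[, b]) + mcse(f2$draws[, b]))
    expect_lt(abs(mean(f1$draws[, b]) - mean(f2$draws[, b])), tol + 1e-3)
  }
})

test_that("flipping the treatment coding leaves predictions invariant", {
  # exchange symmetry: under coding flip the draws map as
  # b0' = b0 + bt, bt' = -bt, bo' = bo + bi, bi' = -bi, bs' = bs,
  # and per-quadrat predicted probabilities are identical
  set.seed(74)
  draws <- cbind(intercept = rnorm(50, -2), treatment = rnorm(50, 1),
                 openness = rnorm(50, 0.01, 0.02),
                 interaction = rnorm(50, -0.05, 0.02),
                 slope = rnorm(50, 0, 0.02))
  flipped <- cbind(intercept = draws[, "intercept"] + draws[, "treatment"],
                   treatment = -draws[, "treatment"],
                   openness = draws[, "openness"] + draws[, "interaction"],
                   interaction = -draws[, "interaction"],
                   slope = draws[, "slope"])
  for (i in c(1, 25, 50)) {
    for (tr in c("exclosure", "grazing")) {
      for (op in c(17, 40, 65)) {
        expect_equal(
          predict_probability(draws[i, ], tr, op, "exclosure_is_1"),
          predict_probability(flipped[i, ], tr, op, "grazing_is_1"),
          tolerance = 1e-12)
      }
    }
  }
})

test_that("effective size and MCSE behave sensibly", {
  set.seed(75)
  iid <- rnorm(4000)
  expect_gt(effective_size(iid), 2000)
  ar <- as.numeric(stats::filter(rnorm(4000), 0.9, method = "recursive"))
  expect_lt(effective_size(ar), 1500)  # strong autocorrelation shrinks ESS
  expect_equal(mcse(iid), sd(iid) / sqrt(effective_size(iid)))
})

test_that("fit outputs can be written and reread", {
  d <- tiny_dataset(seed = 76)
  a <- build_design(d, "seedbank")
  fit <- suppressWarnings(run_mcmc(a, settings = quick_settings(), seed = 77))
  dir <- withr::local_tempdir()
  paths <- write_fit(fit, dir, prefix = "seedbank")
  expect_true(all(file.exists(paths)))
  draws <- read.csv(paths[["draws"]], check.names = FALSE)
  expect_equal(nrow(draws), nrow(fit$draws))
  expect_equal(draws$chain, fit$chain)
  expect_equal(as.matrix(draws[, colnames(fit$draws)]), fit$draws,
               ignore_attr = TRUE, tolerance = 1e-6)
})
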