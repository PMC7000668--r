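#' Prior specification for the hierarchical occurrence model
#'
#' Fixed effects get independent Normal(0, `beta_var`) priors (default
#' variance 10,000, effectively non-informative on the logit scale). Each
#' random-intercept factor gets Normal(0, r) with its own variance
#' hyperparameter r, whose reciprocal 1/r is uniform on (0, `recip_upper`)
#' (default 1e9). That hyperprior implies a density on r proportional to
#' r^-2 on (1/`recip_upper`, Inf), which is what [log_unnormalized_posterior()]
#' and the sampler use, support truncation included.
#'
#' @param beta_var Prior variance of every fixed effect (> 0).
#' @param recip_upper Upper bound of the uniform hyperprior on 1/r (> 0).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_var = 1e4, recip_upper = 1e9) {
  stopifnot(is.numeric(beta_var), beta_var > 0,
            is.numeric(recip_upper), recip_upper > 0)
  structure(list(beta_var = beta_var,
                 recip_upper = recip_upper,
                 r_lower = 1 / recip_upper),
            class = "prior_spec")
}

#' MCMC settings for the Metropolis-within-Gibbs sampler
#'
#' Defaults follow the motivating protocol: three chains of 30,000
#' iterations with a thinning interval of three, retaining the final 3,000
#' thinned draws per chain so the pooled posterior holds 9,000 draws. The
#' burn-in (everything before the retained window) is also the adaptation
#' window: per-block proposal scales are tuned there toward a 20--50%
#' acceptance band and frozen afterwards, preserving detailed balance for
#' the retained draws.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Iterations per chain.
#' @param thin Thinning interval (every `thin`-th iteration kept).
#' @param n_retain Retained draws per chain after thinning; must satisfy
#'   `n_retain * thin <= n_iter`.
#' @param target_accept Acceptance rate targeted by burn-in adaptation.
#' @param init_sd Dispersion scale for overdispersed initial fixed-effect
#'   values (chains start at Normal(0, `init_sd`^2) draws).
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3, n_iter = 30000, thin = 3,
                          n_retain = 3000, target_accept = 0.35,
                          init_sd = 2) {
  check_count(n_chains, "n_chains", min = 1)
  check_count(n_iter, "n_iter", min = 1)
  check_count(thin, "thin", min = 1)
  check_count(n_retain, "n_retain", min = 1)
  if (n_iter < thin) stop("n_iter must be >= thin", call. = FALSE)
  if (n_retain * thin > n_iter) {
    stop("n_retain * thin exceeds n_iter; nothing would be left as burn-in ",
         "or the retained window does not fit", call. = FALSE)
  }
  stopifnot(target_accept > 0, target_accept < 1, init_sd >= 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 thin = as.integer(thin),
                 n_retain = as.integer(n_retain),
                 n_burn_iter = as.integer(n_iter - n_retain * thin),
                 target_accept = target_accept,
                 init_sd = init_sd),
            class = "mcmc_settings")
}

#' Build model-ready arrays from a validated dataset
#'
#' Expands one layer of a dataset to the modelling rows (one per
#' species x quadrat), leaving covariates on their raw measurement scales
#' (openness in percent, slope in degrees) so coefficients are directly
#' comparable across runs. The returned index maps record the factor-level
#' ordering used for the random intercepts.
#'
#' @param dataset An `occu_data` or `synthetic_dataset` (anything holding
#'   `quadrats` and `occurrences` tables). Apply [filter_palatable()] first
#'   if the data contain unpalatable species.
#' @param layer Which occurrence layer to model.
#' @param treatment_coding Which treatment level carries indicator value 1.
#' @return A list of class `model_arrays`: `y` (0/1 outcome vector), `X`
#'   (n x 5 matrix: intercept, treatment, openness, interaction, slope),
#'   `pair_index` and `species_index` (1-based factor codes), `pair_levels`,
#'   `species_levels`, `treatment_coding`, `layer`.
#' @export
#' @examples
#' q <- generate_design(study_design(), seed = 1)
#' d <- simulate_occurrence(q, true_parameters(), 13, "seedbank", seed = 2)
#' a <- build_design(d, "seedbank")
#' dim(a$X)  # 520 x 5
build_design <- function(dataset, layer = c("seedbank", "aboveground"),
                         treatment_coding = c("exclosure_is_1",
                                              "grazing_is_1")) {
  layer <- match.arg(layer)
  treatment_coding <- match.arg(treatment_coding)
  quadrats <- dataset$quadrats
  occ <- dataset$occurrences[dataset$occurrences$layer == layer, ,
                             drop = FALSE]
  if (nrow(occ) == 0) {
    stop("layer '", layer, "' has no occurrence records", call. = FALSE)
  }
  qi <- match(occ$quadrat_id, quadrats$quadrat_id)
  if (anyNA(qi)) {
    stop("occurrence records reference quadrats missing from the quadrat ",
         "table; run validate_dataset() first", call. = FALSE)
  }
  pair_levels <- sort(unique(quadrats$pair_id))
  species_levels <- sort(unique(occ$species_id))
  if (length(pair_levels) < 2) {
    stop("random factor pair_id has a single level; at least 2 site pairs ",
         "are required", call. = FALSE)
  }
  if (length(species_levels) < 2) {
    stop("random factor species_id has a single level; at least 2 species ",
         "are required", call. = FALSE)
  }
  ind <- treatment_indicator(quadrats$treatment[qi], treatment_coding)
  openness <- quadrats$openness_pct[qi]
  slope <- quadrats$slope_deg[qi]
  X <- cbind(intercept = 1, treatment = ind, openness = openness,
             interaction = ind * openness, slope = slope)
  structure(list(y = as.integer(occ$present),
                 X = X,
                 pair_index = match(quadrats$pair_id[qi], pair_levels),
                 species_index = match(occ$species_id, species_levels),
                 pair_levels = pair_levels,
                 species_levels = species_levels,
                 treatment_coding = treatment_coding,
                 layer = layer),
            class = "model_arrays")
}

#' Log unnormalized posterior of the occurrence model
#'
#' Reference implementation of the density the sampler targets:
#' Bernoulli-logit log likelihood, Normal(0, beta_var) log priors on the
#' fixed effects, Normal(0, r) log priors on the random intercepts, and the
#' log hyperprior density of each variance r implied by
#' 1/r ~ Uniform(0, recip_upper) — i.e. log(1/recip_upper) - 2 log r on
#' r > 1/recip_upper, the reciprocal-transform Jacobian included. Returns
#' `-Inf` outside the hyperprior support.
#'
#' @param params A list with `beta` (length-`ncol(X)` numeric), and — when
#'   the arrays carry random factors — `u` (per-pair intercepts), `v`
#'   (per-species intercepts), `r_pair`, `r_species` (variances > 0).
#' @param arrays A `model_arrays` object (or a minimal list with `y`, `X`,
#'   optional `pair_index`/`species_index`).
#' @param prior A [prior_spec()].
#' @return Scalar log density (finite, or `-Inf` outside support).
#' @export
log_unnormalized_posterior <- function(params, arrays,
                                       prior = prior_spec()) {
  beta <- params$beta
  if (any(!is.finite(beta))) stop("non-finite beta", call. = FALSE)
  eta <- as.numeric(arrays$X %*% beta)
  lp <- 0
  has_pair <- !is.null(arrays$pair_index) && length(arrays$pair_index) > 0
  has_species <- !is.null(arrays$species_index) &&
    length(arrays$species_index) > 0
  if (has_pair) {
    if (any(!is.finite(params$u))) stop("non-finite u", call. = FALSE)
    eta <- eta + params$u[arrays$pair_index]
    lp <- lp + random_effect_log_prior(params$u, params$r_pair, prior)
  }
  if (has_species) {
    if (any(!is.finite(params$v))) stop("non-finite v", call. = FALSE)
    eta <- eta + params$v[arrays$species_index]
    lp <- lp + random_effect_log_prior(params$v, params$r_species, prior)
  }
  if (!is.finite(lp)) return(-Inf)
  loglik <- if (length(arrays$y)) {
    sum(arrays$y * eta - log1pexp(eta))
  } else 0
  logprior_beta <- sum(dnorm(beta, 0, sqrt(prior$beta_var), log = TRUE))
  loglik + logprior_beta + lp
}

random_effect_log_prior <- function(effects, r, prior) {
  if (is.null(r) || !is.finite(r) || r <= prior$r_lower) return(-Inf)
  sum(dnorm(effects, 0, sqrt(r), log = TRUE)) +
    log(1 / prior$recip_upper) - 2 * log(r)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance-ratio diagnostic, computed from
#' first principles: with m chains of n draws, W is the mean within-chain
#' variance, B/n the variance of the chain means, and
#' PSRF = sqrt(((n-1)/n * W + B/n) / W). Values near 1 indicate the chains
#' are sampling the same distribution; < 1.1 is the conventional
#' convergence rule.
#'
#' @param chains A numeric matrix (draws in rows, one column per chain) or a
#'   list of equal-length numeric vectors.
#' @return The PSRF scalar. If every chain is constant the parameter is
#'   degenerate: returns 1 (with a warning) when all chains share the same
#'   constant, `Inf` when they disagree.
#' @export
#' @examples
#' set.seed(1)
#' gelman_rubin(matrix(rnorm(2000), ncol = 2))   # ~1
#' gelman_rubin(cbind(rnorm(100, -10), rnorm(100, 10)))  # >> 1.1
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) stop("gelman_rubin needs >= 2 chains", call. = FALSE)
  if (n < 10) stop("gelman_rubin needs >= 10 draws per chain", call. = FALSE)
  W <- mean(apply(chains, 2, var))
  chain_means <- colMeans(chains)
  B_over_n <- var(chain_means)
  if (W == 0) {
    if (B_over_n == 0) {
      warning("all chains constant and equal; PSRF defined as 1",
              call. = FALSE)
      return(1)
    }
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Summarize fixed-effect posteriors
#'
#' Per fixed effect: posterior median and 2.5/97.5 percentiles of the pooled
#' retained draws (linear interpolation between order statistics, R's
#' default quantile type 7), plus a significance flag set when the 95%
#' credible interval excludes zero.
#'
#' @param fit An `occu_fit` from [run_mcmc()], or a draws matrix whose
#'   columns include the fixed effects.
#' @param parameters Which columns to summarize (default: the fixed
#'   effects of the fit, or all columns of a bare matrix).
#' @return A data frame of class `coefficient_summary` with columns
#'   `coefficient`, `median`, `q2.5`, `q97.5`, `significant`.
#' @export
summarize_posterior <- function(fit, parameters = NULL) {
  draws <- if (inherits(fit, "occu_fit")) fit$draws else as.matrix(fit)
  if (nrow(draws) == 0) stop("no posterior draws to summarize", call. = FALSE)
  if (is.null(parameters)) {
    parameters <- if (inherits(fit, "occu_fit")) fit$fixed_names
                  else colnames(draws)
  }
  qs <- t(apply(draws[, parameters, drop = FALSE], 2, quantile,
                probs = c(0.025, 0.5, 0.975), names = FALSE, type = 7))
  out <- data.frame(coefficient = parameters,
                    median = qs[, 2],
                    q2.5 = qs[, 1],
                    q97.5 = qs[, 3],
                    stringsAsFactors = FALSE)
  out$significant <- out$q2.5 > 0 | out$q97.5 < 0
  rownames(out) <- NULL
  class(out) <- c("coefficient_summary", "data.frame")
  out
}

#' Effective sample size of an MCMC trace
#'
#' n / (1 + 2 * sum of autocorrelations), with the sum truncated by Geyer's
#' initial positive sequence rule (pairs of successive autocorrelations are
#' accumulated while their sum stays positive). Used to turn posterior SDs
#' into Monte Carlo standard errors.
#'
#' @param x Numeric vector of draws from one (pooled) trace.
#' @return Effective sample size, capped at `length(x)`.
#' @export
effective_size <- function(x) {
  n <- length(x)
  if (n < 4 || var(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 2000), plot = FALSE,
             demean = TRUE)$acf[-1]
  # Geyer initial positive sequence on Gamma_k = rho_{2k} + rho_{2k+1}
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    gam <- rho[k] + rho[k + 1]
    if (gam <= 0) break
    s <- s + gam
    k <- k + 2
  }
  max(1, min(n, n / (1 + 2 * s)))
}

#' Monte Carlo standard error of a posterior mean
#'
#' @param x Numeric vector of draws.
#' @return `sd(x) / sqrt(effective_size(x))`.
#' @export
mcse <- function(x) sd(x) / sqrt(effective_size(x))

#' @importFrom stats dnorm
NULL
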