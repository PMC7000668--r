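#' Describe a paired exclosure/grazing study design
#'
#' Captures the sampling layout of a paired-plot grazing study: `n_pairs`
#' exclosure/grazing plot pairs, each plot divided into
#' `quadrats_per_plot` quadrats, with canopy openness varying mostly between
#' pairs (a pair-level mean drawn uniformly on `openness_range`, quadrats
#' jittered around it) and slope varying per quadrat. Defaults mirror a
#' 5-pair, 4-quadrat-per-plot survey (40 quadrats) spanning 17--65% canopy
#' openness, with 13 palatable species in the seed bank and 36 aboveground.
#'
#' @param n_pairs Number of exclosure/grazing plot pairs (>= 2 for model
#'   fitting; >= 1 to generate).
#' @param quadrats_per_plot Quadrats per plot (each pair contributes
#'   `2 * quadrats_per_plot` quadrats).
#' @param openness_range Numeric length-2, percent canopy openness bounds
#'   within \[0, 100\].
#' @param openness_within_pair_sd SD (percentage points) of the Normal jitter
#'   of quadrat openness around its pair-level mean; jittered values are
#'   clamped to `openness_range`.
#' @param slope_range Numeric length-2, ground-slope bounds in degrees
#'   (non-negative); quadrat slopes are uniform on this interval.
#' @param n_species Named integer vector of species counts per layer,
#'   e.g. `c(seedbank = 13, aboveground = 36)`.
#' @param layers Character subset of `c("seedbank", "aboveground")`.
#' @return An object of class `study_design`.
#' @export
#' @examples
#' study_design()
#' study_design(n_pairs = 2, quadrats_per_plot = 1)
study_design <- function(n_pairs = 5,
                         quadrats_per_plot = 4,
                         openness_range = c(17, 65),
                         openness_within_pair_sd = 5,
                         slope_range = c(0, 30),
                         n_species = c(seedbank = 13, aboveground = 36),
                         layers = c("seedbank", "aboveground")) {
  check_count(n_pairs, "n_pairs", min = 1)
  check_count(quadrats_per_plot, "quadrats_per_plot", min = 1)
  check_interval(openness_range, "openness_range", lower = 0, upper = 100)
  if (!is.numeric(openness_within_pair_sd) || length(openness_within_pair_sd) != 1 ||
      openness_within_pair_sd < 0) {
    stop("openness_within_pair_sd must be a single non-negative number",
         call. = FALSE)
  }
  check_interval(slope_range, "slope_range", lower = 0, upper = Inf)
  layers <- match.arg(layers, c("seedbank", "aboveground"), several.ok = TRUE)
  if (is.null(names(n_species)) || !all(layers %in% names(n_species))) {
    stop("n_species must be named with an entry for every layer in 'layers'",
         call. = FALSE)
  }
  for (ly in layers) check_count(n_species[[ly]], paste0("n_species[", ly, "]"),
                                 min = 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 quadrats_per_plot = as.integer(quadrats_per_plot),
                 openness_range = as.numeric(openness_range),
                 openness_within_pair_sd = as.numeric(openness_within_pair_sd),
                 slope_range = as.numeric(slope_range),
                 n_species = n_species[layers],
                 layers = layers),
            class = "study_design")
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("%s must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(TRUE)
}

check_interval <- function(x, name, lower, upper) {
  if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || x[1] > x[2] ||
      x[1] < lower || x[2] > upper) {
    stop(sprintf("%s must be an ordered interval within [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Generative coefficients for the occurrence simulator
#'
#' The logit-scale truth used by [simulate_occurrence()] and targeted by
#' parameter-recovery experiments. The five fixed effects correspond to the
#' occurrence model's intercept, treatment indicator, canopy openness (per
#' percentage point), treatment-by-openness interaction, and slope (per
#' degree); `sigma_pair` and `sigma_species` are the standard deviations of
#' the site-pair and species random intercepts. Defaults place the fixed
#' effects at the fitted seed-bank posterior medians of the motivating study
#' (intercept -3.4, treatment 1.95, openness 0.01, interaction -0.07,
#' slope -0.061); no fitted random-effect variances were reported, so the
#' default SDs are set to 1.0 on the logit scale and are fully configurable.
#'
#' @param intercept,treatment,openness,interaction,slope Logit-scale fixed
#'   effects.
#' @param sigma_pair,sigma_species Non-negative random-intercept SDs.
#' @param treatment_coding Which treatment level carries indicator value 1:
#'   `"exclosure_is_1"` (default) or `"grazing_is_1"`.
#' @return An object of class `true_parameters`.
#' @export
true_parameters <- function(intercept = -3.4,
                            treatment = 1.95,
                            openness = 0.01,
                            interaction = -0.07,
                            slope = -0.061,
                            sigma_pair = 1.0,
                            sigma_species = 1.0,
                            treatment_coding = c("exclosure_is_1",
                                                 "grazing_is_1")) {
  treatment_coding <- match.arg(treatment_coding)
  betas <- c(intercept = intercept, treatment = treatment,
             openness = openness, interaction = interaction, slope = slope)
  if (!is.numeric(betas) || any(!is.finite(betas))) {
    stop("all fixed-effect coefficients must be finite numbers", call. = FALSE)
  }
  if (sigma_pair < 0) stop("sigma_pair must be >= 0", call. = FALSE)
  if (sigma_species < 0) stop("sigma_species must be >= 0", call. = FALSE)
  structure(list(beta = betas,
                 sigma_pair = as.numeric(sigma_pair),
                 sigma_species = as.numeric(sigma_species),
                 treatment_coding = treatment_coding),
            class = "true_parameters")
}

#' Generate quadrat records for a study design
#'
#' Lays out `n_pairs * 2 * quadrats_per_plot` quadrats. For each pair a mean
#' canopy openness is drawn uniformly on the design's openness range; every
#' quadrat in both plots of the pair gets that mean plus Normal jitter
#' (clamped to the range). Slopes are uniform on the slope range per quadrat.
#' All draws come from a single stream seeded by `seed`, so the output is
#' reproducible bit-for-bit.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A data frame of quadrat records with columns `quadrat_id`,
#'   `pair_id`, `treatment` (`"exclosure"`/`"grazing"`), `openness_pct`,
#'   `slope_deg`.
#' @export
#' @examples
#' q <- generate_design(study_design(), seed = 1)
#' nrow(q)          # 40
#' table(q$treatment)
generate_design <- function(design, seed) {
  stopifnot(inherits(design, "study_design"))
  check_count(seed, "seed")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  pair_ids <- sprintf("pair%02d", seq_len(design$n_pairs))
  pair_mean_open <- runif(design$n_pairs, design$openness_range[1],
                          design$openness_range[2])
  treatments <- c("exclosure", "grazing")
  rows <- vector("list", design$n_pairs * 2L)
  k <- 0L
  for (p in seq_len(design$n_pairs)) {
    for (tr in treatments) {
      k <- k + 1L
      open <- pair_mean_open[p] +
        rnorm(design$quadrats_per_plot, 0, design$openness_within_pair_sd)
      open <- pmin(pmax(open, design$openness_range[1]),
                   design$openness_range[2])
      slope <- runif(design$quadrats_per_plot, design$slope_range[1],
                     design$slope_range[2])
      rows[[k]] <- data.frame(
        quadrat_id = sprintf("%s_%s_q%d", pair_ids[p], substr(tr, 1, 4),
                             seq_len(design$quadrats_per_plot)),
        pair_id = pair_ids[p],
        treatment = tr,
        openness_pct = open,
        slope_deg = slope,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# save/restore the global RNG state so seeded generators are side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Occurrence probability under the generative model
#'
#' Inverse-logit of the fixed-effect linear predictor (random intercepts
#' zero). Useful for calibration checks and as the plug-in predictor of the
#' severity step.
#'
#' @param truth A [true_parameters()] (or any object with a 5-vector `$beta`
#'   and `$treatment_coding`).
#' @param treatment `"exclosure"` or `"grazing"`.
#' @param openness Canopy openness in percent.
#' @param slope Slope in degrees (default 0).
#' @return Occurrence probability in (0, 1).
#' @export
occurrence_probability <- function(truth, treatment, openness, slope = 0) {
  ind <- treatment_indicator(treatment, truth$treatment_coding)
  b <- truth$beta
  plogis(b[["intercept"]] + b[["treatment"]] * ind +
           b[["openness"]] * openness +
           b[["interaction"]] * ind * openness +
           b[["slope"]] * slope)
}

treatment_indicator <- function(treatment, treatment_coding) {
  if (!treatment_coding %in% c("exclosure_is_1", "grazing_is_1")) {
    stop("unknown treatment_coding: ", treatment_coding, call. = FALSE)
  }
  one <- if (treatment_coding == "exclosure_is_1") "exclosure" else "grazing"
  as.numeric(treatment == one)
}

#' Simulate a presence/absence dataset over a set of quadrats
#'
#' Draws one random intercept per site pair from Normal(0, sigma_pair^2) and
#' one per species from Normal(0, sigma_species^2), then for every
#' species x quadrat cell computes the logit-scale linear predictor and draws
#' a Bernoulli occurrence. All randomness flows from one stream seeded by
#' `seed` in a fixed order: pair effects, species effects, then outcomes
#' row-major by species then quadrat, making datasets portable across runs.
#'
#' @param quadrats Quadrat records from [generate_design()] (or read in via
#'   [read_dataset()]).
#' @param truth A [true_parameters()].
#' @param n_species Number of species to simulate in this layer.
#' @param layer `"seedbank"` or `"aboveground"`.
#' @param seed Integer seed.
#' @return An object of class `synthetic_dataset`: a list with `quadrats`,
#'   `occurrences` (long-format presence/absence), `species` (all palatable),
#'   `truth`, `layer` and `seed`.
#' @export
#' @examples
#' q <- generate_design(study_design(), seed = 1)
#' d <- simulate_occurrence(q, true_parameters(), n_species = 13,
#'                          layer = "seedbank", seed = 2)
#' nrow(d$occurrences)  # 13 * 40
simulate_occurrence <- function(quadrats, truth, n_species,
                                layer = c("seedbank", "aboveground"), seed) {
  layer <- match.arg(layer)
  stopifnot(is.data.frame(quadrats), nrow(quadrats) > 0)
  if (!inherits(truth, "true_parameters")) {
    stop("truth must be a true_parameters object", call. = FALSE)
  }
  check_count(n_species, "n_species", min = 1)
  check_count(seed, "seed")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  pair_levels <- unique(quadrats$pair_id)
  species_ids <- sprintf("sp%02d_%s", seq_len(n_species), substr(layer, 1, 2))
  u_pair <- rnorm(length(pair_levels), 0, truth$sigma_pair)
  v_species <- rnorm(n_species, 0, truth$sigma_species)
  names(u_pair) <- pair_levels

  ind <- treatment_indicator(quadrats$treatment, truth$treatment_coding)
  b <- truth$beta
  eta_quadrat <- b[["intercept"]] + b[["treatment"]] * ind +
    b[["openness"]] * quadrats$openness_pct +
    b[["interaction"]] * ind * quadrats$openness_pct +
    b[["slope"]] * quadrats$slope_deg +
    u_pair[quadrats$pair_id]

  nq <- nrow(quadrats)
  occ <- data.frame(
    quadrat_id = rep(quadrats$quadrat_id, times = n_species),
    species_id = rep(species_ids, each = nq),
    layer = layer,
    present = NA_integer_,
    stringsAsFactors = FALSE
  )
  # outcomes row-major by species then quadrat, one Bernoulli draw per cell
  p <- plogis(rep(eta_quadrat, times = n_species) +
                rep(v_species, each = nq))
  occ$present <- rbinom(nq * n_species, 1L, p)

  structure(list(quadrats = quadrats,
                 occurrences = occ,
                 species = data.frame(species_id = species_ids,
                                      palatable = 1L,
                                      stringsAsFactors = FALSE),
                 truth = truth,
                 layer = layer,
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' Simulate a full study (design plus one or two occurrence layers)
#'
#' Convenience wrapper: generates quadrats from `design` and simulates every
#' layer listed in the design, with per-layer seeds derived deterministically
#' from `seed`.
#'
#' @inheritParams generate_design
#' @param truth A [true_parameters()].
#' @return A named list of `synthetic_dataset` objects (one per layer) with
#'   the shared `quadrats` attached as an attribute.
#' @export
simulate_study <- function(design, truth, seed) {
  quadrats <- generate_design(design, seed)
  out <- lapply(seq_along(design$layers), function(i) {
    ly <- design$layers[i]
    simulate_occurrence(quadrats, truth, design$n_species[[ly]], ly,
                        seed = seed + 1000L * i)
  })
  names(out) <- design$layers
  attr(out, "quadrats") <- quadrats
  out
}

#' Parameter-recovery experiment
#'
#' Simulates `n_replicates` datasets under `truth`, fits each with
#' [run_mcmc()], and summarizes recovery of the five fixed effects:
#' per-coefficient bias and RMSE of the posterior median, and empirical
#' coverage of the 95% credible interval. Replicates that fail the
#' Gelman-Rubin convergence rule are flagged in the output, never dropped.
#'
#' @param design A [study_design()] (a single layer is used; see `layer`).
#' @param truth A [true_parameters()].
#' @param n_replicates Number of simulated datasets (>= 1).
#' @param settings [mcmc_settings()] used for every fit.
#' @param seed Integer master seed; replicate seeds are derived from it.
#' @param layer Which design layer to simulate and fit.
#' @return A list of class `recovery_summary` with elements `replicates`
#'   (one row per replicate x coefficient: estimate, CI, covered, converged)
#'   and `summary` (per-coefficient bias, RMSE, coverage, n_converged).
#' @export
recovery_experiment <- function(design, truth, n_replicates = 20,
                                settings = mcmc_settings(), seed = 1,
                                layer = "seedbank") {
  check_count(n_replicates, "n_replicates", min = 1)
  truth_beta <- truth$beta
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- seed + 7919L * r  # deterministic, well-separated streams
    quadrats <- generate_design(design, rep_seed)
    ds <- simulate_occurrence(quadrats, truth, design$n_species[[layer]],
                              layer, seed = rep_seed + 1L)
    arrays <- build_design(ds, layer = layer,
                           treatment_coding = truth$treatment_coding)
    fit <- run_mcmc(arrays, settings = settings, seed = rep_seed + 2L)
    sm <- summarize_posterior(fit)
    reps[[r]] <- data.frame(
      replicate = r,
      coefficient = sm$coefficient,
      truth = as.numeric(truth_beta[sm$coefficient]),
      estimate = sm$median,
      ci_lo = sm$q2.5,
      ci_hi = sm$q97.5,
      covered = sm$q2.5 <= truth_beta[sm$coefficient] &
        truth_beta[sm$coefficient] <= sm$q97.5,
      converged = fit$convergence$pass,
      max_psrf = max(fit$convergence$psrf$psrf),
      stringsAsFactors = FALSE
    )
  }
  replicates <- do.call(rbind, reps)
  rownames(replicates) <- NULL
  agg <- split(replicates, replicates$coefficient)
  summary <- do.call(rbind, lapply(agg, function(d) {
    data.frame(coefficient = d$coefficient[1],
               truth = d$truth[1],
               bias = mean(d$estimate - d$truth),
               rmse = sqrt(mean((d$estimate - d$truth)^2)),
               coverage = mean(d$covered),
               n_converged = sum(d$converged),
               n_replicates = nrow(d),
               stringsAsFactors = FALSE)
  }))
  summary <- summary[match(names(truth_beta), summary$coefficient), ]
  rownames(summary) <- NULL
  if (any(!replicates$converged)) {
    warning(sum(!replicates$converged & !duplicated(replicates$replicate)),
            " replicate(s) failed the PSRF < 1.1 convergence rule; ",
            "flagged in the output", call. = FALSE)
  }
  structure(list(replicates = replicates, summary = summary),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("Parameter-recovery experiment:",
      max(x$replicates$replicate), "replicates\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
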