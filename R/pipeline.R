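#' Assemble and validate a pipeline run configuration
#'
#' A run is configured by a YAML file or an equivalent named list. Exactly
#' one of `input` (paths to the three CSV tables) or `simulate` (a block of
#' [study_design()] and [true_parameters()] overrides) must be present.
#' Remaining blocks override defaults: `mcmc` ([mcmc_settings()] arguments),
#' `prior` ([prior_spec()] arguments), `grid` ([openness_grid()] arguments),
#' plus `layer` (`"seedbank"`, `"aboveground"` or `"both"`),
#' `treatment_coding`, `out` (output directory) and `seed`.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim) {
    stop("config must contain exactly one of 'input' (csv paths) or ",
         "'simulate' (design + truth block)", call. = FALSE)
  }
  if (has_input) {
    need <- c("quadrats", "occurrences", "species")
    missing <- setdiff(need, names(config$input))
    if (length(missing)) {
      stop("config$input missing path(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  config$layer <- match.arg(config$layer %||% "seedbank",
                            c("seedbank", "aboveground", "both"))
  config$treatment_coding <- match.arg(
    config$treatment_coding %||% "exclosure_is_1",
    c("exclosure_is_1", "grazing_is_1"))
  config$seed <- as.integer(config$seed %||% 1L)
  config$out <- config$out %||% "grazesev_run"
  config$allow_nonconverged <- isTRUE(config$allow_nonconverged)
  # materialize typed sub-configs now so bad overrides fail fast
  design_args <- as_design_args(config$simulate)
  if (is.null(design_args$layers)) {
    design_args$layers <- if (config$layer == "both")
      c("seedbank", "aboveground") else config$layer
  }
  config$.design <- do.call(study_design, design_args)
  config$.truth <- do.call(
    true_parameters,
    c(as_list(config$simulate$truth),
      list(treatment_coding = config$treatment_coding)))
  config$.settings <- do.call(mcmc_settings, as_list(config$mcmc))
  config$.prior <- do.call(prior_spec, as_list(config$prior))
  config$.grid <- do.call(openness_grid, as_list(config$grid))
  structure(config, class = "run_config")
}

as_list <- function(x) if (is.null(x)) list() else as.list(x)

as_design_args <- function(sim) {
  args <- as_list(sim$design)
  if (!is.null(args$n_species)) args$n_species <- unlist(args$n_species)
  for (f in c("openness_range", "slope_range")) {
    if (!is.null(args[[f]])) args[[f]] <- as.numeric(unlist(args[[f]]))
  }
  args
}

config_layers <- function(config) {
  if (config$layer == "both") c("seedbank", "aboveground") else config$layer
}

#' Simulate a synthetic study to disk
#'
#' Generates the quadrat layout and per-layer occurrence tables from the
#' config's `simulate` block and writes the three CSV schemas plus the
#' generative truth and a reproducibility manifest under `config$out`.
#'
#' @param config A [run_config()] (or something coercible to one).
#' @return Invisibly, the named vector of paths written.
#' @export
pipeline_simulate <- function(config) {
  config <- as_run_config(config)
  if (is.null(config$simulate)) {
    stop("pipeline_simulate needs a config with a 'simulate' block",
         call. = FALSE)
  }
  layers <- config_layers(config)
  design <- config$.design
  design$layers <- layers
  design$n_species <- design$n_species[layers]
  study <- simulate_study(design, config$.truth, config$seed)
  combined <- list(
    quadrats = attr(study, "quadrats"),
    occurrences = do.call(rbind, lapply(study, `[[`, "occurrences")),
    species = do.call(rbind, lapply(study, `[[`, "species"))
  )
  paths <- write_dataset(combined, config$out)
  truth_path <- file.path(config$out, "truth.txt")
  write_truth(config$.truth, config$seed, truth_path)
  paths <- c(paths, truth = truth_path)
  log_line(config, "simulate: wrote %d quadrats, %d occurrence records (%s)",
           nrow(combined$quadrats), nrow(combined$occurrences),
           paste(layers, collapse = "+"))
  write_manifest(config, "simulate", paths)
  invisible(paths)
}

#' Fit the occurrence model for each selected layer
#'
#' Reads the dataset (from `config$input`, or the files a previous
#' [pipeline_simulate()] left under `config$out`), applies the palatability
#' filter, builds the design arrays, runs the MCMC and writes draws,
#' convergence table and coefficient summary per layer. Fails on a
#' Gelman-Rubin convergence failure unless `config$allow_nonconverged`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of `occu_fit` objects (one per layer).
#' @export
pipeline_fit <- function(config) {
  config <- as_run_config(config)
  ds <- load_config_dataset(config)
  occ <- filter_palatable(ds$occurrences, ds$species, quiet = TRUE)
  fits <- list()
  all_paths <- character(0)
  for (i in seq_along(config_layers(config))) {
    ly <- config_layers(config)[i]
    arrays <- build_design(list(quadrats = ds$quadrats, occurrences = occ),
                           layer = ly,
                           treatment_coding = config$treatment_coding)
    fit <- withCallingHandlers(
      run_mcmc(arrays, prior = config$.prior, settings = config$.settings,
               seed = config$seed + 101L * i),
      warning = function(w) {
        log_line(config, "fit[%s]: %s", ly, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    log_line(config,
             "fit[%s]: %d rows, %d draws, max PSRF %.3f, accept beta %.2f",
             ly, length(arrays$y), nrow(fit$draws),
             max(fit$convergence$psrf$psrf), fit$accept[["beta"]])
    if (!fit$convergence$pass && !config$allow_nonconverged) {
      stop("MCMC for layer '", ly, "' failed the PSRF < 1.1 rule; rerun ",
           "with more iterations or set allow_nonconverged", call. = FALSE)
    }
    paths <- write_fit(fit, config$out, prefix = ly)
    all_paths <- c(all_paths, paths)
    fits[[ly]] <- fit
  }
  write_manifest(config, "fit", all_paths)
  invisible(fits)
}

#' Compute and write severity curves from saved draws
#'
#' Consumes the per-layer draws a previous [pipeline_fit()] wrote under
#' `config$out` (or takes fits directly), evaluates the grazing-severity
#' ratio over the configured openness grid and writes curve CSVs, reports
#' and figures suffixed by layer.
#'
#' @param config A [run_config()].
#' @param fits Optional named list of `occu_fit` objects to use instead of
#'   reading draw files.
#' @return Invisibly, a named list of `severity_curve` objects.
#' @export
pipeline_severity <- function(config, fits = NULL) {
  config <- as_run_config(config)
  curves <- list()
  all_paths <- character(0)
  for (ly in config_layers(config)) {
    draws <- if (!is.null(fits)) {
      fits[[ly]]$draws
    } else {
      path <- file.path(config$out, paste0(ly, "_draws.csv"))
      if (!file.exists(path)) {
        stop("no saved draws at ", path, "; run pipeline_fit first",
             call. = FALSE)
      }
      as.matrix(read.csv(path, check.names = FALSE)[, -(1:2)])
    }
    curve <- severity_curve(draws, grid = config$.grid,
                            treatment_coding = config$treatment_coding)
    thr <- attr(curve, "threshold")
    log_line(config, "severity[%s]: %d grid points, threshold %s", ly,
             nrow(curve), if (is.na(thr)) "none" else paste0(thr, "%"))
    paths <- curve_report(curve, config$out, layer = ly)
    all_paths <- c(all_paths, paths)
    curves[[ly]] <- curve
  }
  write_manifest(config, "severity", all_paths)
  invisible(curves)
}

#' Run a parameter-recovery experiment from a config
#'
#' Simulates and refits `n_replicates` datasets at the config's generative
#' truth and writes per-replicate and per-coefficient summaries.
#'
#' @param config A [run_config()] with a `simulate` block; the optional
#'   `recover` block may set `n_replicates` (default 20).
#' @return Invisibly, the `recovery_summary`.
#' @export
pipeline_recover <- function(config) {
  config <- as_run_config(config)
  if (is.null(config$simulate)) {
    stop("pipeline_recover needs a config with a 'simulate' block",
         call. = FALSE)
  }
  n_rep <- config$recover$n_replicates %||% 20
  layer <- config_layers(config)[1]
  rec <- recovery_experiment(config$.design, config$.truth,
                             n_replicates = n_rep,
                             settings = config$.settings,
                             seed = config$seed, layer = layer)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  paths <- c(replicates = file.path(config$out, "recovery_replicates.csv"),
             summary = file.path(config$out, "recovery_summary.csv"))
  write.csv(rec$replicates, paths[["replicates"]], row.names = FALSE,
            quote = FALSE)
  write.csv(rec$summary, paths[["summary"]], row.names = FALSE,
            quote = FALSE)
  log_line(config, "recover: %d replicates, coverage %s", n_rep,
           paste(sprintf("%s=%.2f", rec$summary$coefficient,
                         rec$summary$coverage), collapse = " "))
  write_manifest(config, "recover", paths)
  invisible(rec)
}

#' Run the full pipeline (simulate, fit, severity) from one config
#'
#' @param config A [run_config()] with a `simulate` block.
#' @return Invisibly, a list with the fits and severity curves.
#' @export
pipeline_all <- function(config) {
  config <- as_run_config(config)
  pipeline_simulate(config)
  fits <- pipeline_fit(config)
  curves <- pipeline_severity(config, fits = fits)
  invisible(list(fits = fits, curves = curves))
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) config else run_config(config)
}

load_config_dataset <- function(config) {
  if (!is.null(config$input)) {
    read_dataset(config$input$quadrats, config$input$occurrences,
                 config$input$species, quiet = TRUE)
  } else {
    paths <- file.path(config$out, c("quadrats.csv", "occurrences.csv",
                                     "species.csv"))
    if (!all(file.exists(paths))) {
      stop("no input paths configured and no simulated dataset found under ",
           config$out, "; run pipeline_simulate first", call. = FALSE)
    }
    read_dataset(paths[1], paths[2], paths[3], quiet = TRUE)
  }
}

# timestamped, leveled log line to console and <out>/run.log
log_line <- function(config, fmt, ..., level = "INFO") {
  msg <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 level, sprintf(fmt, ...))
  message(msg)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  cat(msg, "\n", sep = "", file = file.path(config$out, "run.log"),
      append = TRUE)
}

# config echo + seeds + version + input checksums: enough to reproduce a run
write_manifest <- function(config, stage, paths) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  public <- config[!startsWith(names(config), ".")]
  files <- unlist(paths)
  files <- files[file.exists(files)]
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    grazesev_version = as.character(packageVersion("grazesev")),
    r_version = R.version.string,
    seed = config$seed,
    config = public,
    files = as.list(setNames(unname(tools::md5sum(files)), files))
  )
  yaml::write_yaml(manifest,
                   file.path(config$out,
                             paste0("manifest_", stage, ".yaml")))
  invisible(manifest)
}
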