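#' Canopy-openness evaluation grid
#'
#' Integer-stepped grid of canopy-openness values on which the severity
#' ratio is evaluated; defaults to every 1% from 17 to 65 (49 points), the
#' observed openness range of the motivating survey. Endpoints inclusive.
#'
#' @param lower,upper Percent canopy openness bounds (lower < upper).
#' @param step Grid step in percentage points (> 0).
#' @return Numeric vector of grid points.
#' @export
openness_grid <- function(lower = 17, upper = 65, step = 1) {
  if (!(lower < upper) || step <= 0) {
    stop("openness_grid needs lower < upper and step > 0", call. = FALSE)
  }
  if (lower < 0 || upper > 100) {
    stop("openness grid must lie within [0, 100]%", call. = FALSE)
  }
  seq(lower, upper, by = step)
}

#' Predicted occurrence probability from one posterior draw
#'
#' Plug-in predictor of the severity step: inverse-logit of the fixed-effect
#' linear predictor with the slope term set to zero and all random
#' intercepts excluded, evaluated for one treatment level at given canopy
#' openness.
#'
#' @param draw Named numeric vector holding at least `intercept`,
#'   `treatment`, `openness`, `interaction` (one row of an `occu_fit`'s
#'   draws).
#' @param treatment `"exclosure"` or `"grazing"`.
#' @param openness Canopy openness in percent, within \[0, 100\] (vectorized).
#' @param treatment_coding Which treatment level the indicator marks.
#' @return Occurrence probability (vector along `openness`).
#' @export
#' @examples
#' medians <- c(intercept = -3.4, treatment = 1.95, openness = 0.01,
#'              interaction = -0.07, slope = -0.061)
#' predict_probability(medians, "grazing", 65)    # ~0.0601
#' predict_probability(medians, "exclosure", 65)  # ~0.00473
predict_probability <- function(draw, treatment, openness,
                                treatment_coding = "exclosure_is_1") {
  if (any(openness < 0 | openness > 100)) {
    stop("openness must lie within [0, 100]%", call. = FALSE)
  }
  ind <- treatment_indicator(treatment, treatment_coding)
  plogis(draw[["intercept"]] + draw[["treatment"]] * ind +
           (draw[["openness"]] + draw[["interaction"]] * ind) * openness)
}

#' Grazing-severity ratio curve with credible bands
#'
#' For every retained posterior draw and every grid point, computes the
#' ratio of predicted occurrence probability in exclosure versus grazing
#' plots (slope zero, random effects excluded), then summarizes across
#' draws: the mean of the ratio and its 2.5/97.5 percentile credible band
#' per grid point. The threshold is the smallest grid openness at which the
#' 2.5% quantile exceeds one, i.e. where the exclosure probability is
#' credibly larger than the grazing probability; `NA` if the band never
#' clears one. Draws whose grazing-side probability underflows to zero are
#' excluded at that grid point and counted.
#'
#' @param fit An `occu_fit`, or a draws matrix with the five fixed-effect
#'   columns.
#' @param grid An [openness_grid()].
#' @param treatment_coding Indicator coding used when predicting (defaults
#'   to the fit's own coding).
#' @param direction `"exclosure_over_grazing"` (default, ratio > 1 means
#'   occurrence is more probable inside the exclosure) or its reciprocal
#'   `"grazing_over_exclosure"`.
#' @param lower_tail Also scan for the openness at which the 97.5% quantile
#'   drops below one (off by default).
#' @return A data frame of class `severity_curve` with columns
#'   `openness_pct`, `mean_ratio`, `ci_lo`, `ci_hi`, and attributes
#'   `threshold` (grid openness or `NA`), `direction`, `n_draws`,
#'   `n_excluded` (underflowed draw x gridpoint pairs), and, when
#'   `lower_tail`, `threshold_lower`.
#' @export
severity_curve <- function(fit, grid = openness_grid(),
                           treatment_coding = NULL,
                           direction = c("exclosure_over_grazing",
                                         "grazing_over_exclosure"),
                           lower_tail = FALSE) {
  direction <- match.arg(direction)
  draws <- if (inherits(fit, "occu_fit")) fit$draws else as.matrix(fit)
  if (nrow(draws) == 0) stop("no posterior draws", call. = FALSE)
  if (is.null(treatment_coding)) {
    treatment_coding <- (if (inherits(fit, "occu_fit"))
      fit$treatment_coding else NULL) %||% "exclosure_is_1"
  }
  need <- c("intercept", "treatment", "openness", "interaction")
  if (!all(need %in% colnames(draws))) {
    stop("draws must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  b0 <- draws[, "intercept"]; bt <- draws[, "treatment"]
  bo <- draws[, "openness"]; bi <- draws[, "interaction"]
  ind_ex <- treatment_indicator("exclosure", treatment_coding)
  ind_gr <- 1 - ind_ex

  n_excluded <- 0L
  summarize_point <- function(x) {
    # draws x grid-point ratios; exclude draws whose denominator underflowed
    eta_ex <- b0 + bt * ind_ex + (bo + bi * ind_ex) * x
    eta_gr <- b0 + bt * ind_gr + (bo + bi * ind_gr) * x
    p_ex <- plogis(eta_ex); p_gr <- plogis(eta_gr)
    num <- if (direction == "exclosure_over_grazing") p_ex else p_gr
    den <- if (direction == "exclosure_over_grazing") p_gr else p_ex
    bad <- den == 0
    if (any(bad)) {
      n_excluded <<- n_excluded + sum(bad)
      num <- num[!bad]; den <- den[!bad]
    }
    ratio <- num / den
    c(mean(ratio), quantile(ratio, c(0.025, 0.975), names = FALSE, type = 7))
  }
  stats <- vapply(grid, summarize_point, numeric(3))
  out <- data.frame(openness_pct = grid,
                    mean_ratio = stats[1, ],
                    ci_lo = stats[2, ],
                    ci_hi = stats[3, ])
  if (n_excluded > 0) {
    message(n_excluded,
            " draw x grid-point ratio(s) excluded (denominator underflow)")
  }
  above <- which(out$ci_lo > 1)
  attr(out, "threshold") <- if (length(above)) grid[above[1]] else NA_real_
  if (lower_tail) {
    below <- which(out$ci_hi < 1)
    attr(out, "threshold_lower") <-
      if (length(below)) grid[below[1]] else NA_real_
  }
  attr(out, "direction") <- direction
  attr(out, "treatment_coding") <- treatment_coding
  attr(out, "n_draws") <- nrow(draws)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("severity_curve", "data.frame")
  out
}

#' @export
print.severity_curve <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf(
    "Grazing-severity curve (%s), %d grid points, %d posterior draws\n",
    attr(x, "direction"), nrow(x), attr(x, "n_draws")))
  cat(if (is.na(thr)) "  95% CI never clears 1\n" else
    sprintf("  95%% CI lower bound exceeds 1 from %g%% canopy openness\n",
            thr))
  print.data.frame(head(as.data.frame(x), 5), row.names = FALSE, digits = 3)
  if (nrow(x) > 5) cat("  ... (", nrow(x) - 5, " more rows)\n", sep = "")
  invisible(x)
}

#' Write severity-curve outputs
#'
#' Writes the curve as CSV (`openness_pct, mean_ratio, ci_lo, ci_hi`), a
#' small text report with the detected threshold, and a figure with the
#' posterior-mean line and 95% credible band.
#'
#' @param curve A [severity_curve()].
#' @param dir Output directory.
#' @param layer Suffix for the filenames (e.g. `"seedbank"`).
#' @param summary Optional [summarize_posterior()] table echoed into the
#'   report.
#' @param figure Write the figure (PDF) alongside the CSV.
#' @return Invisibly, the named vector of paths written.
#' @export
curve_report <- function(curve, dir, layer = "seedbank", summary = NULL,
                         figure = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(curve = file.path(dir, paste0("severity_", layer, ".csv")),
             report = file.path(dir, paste0("severity_", layer,
                                            "_report.txt")))
  write.csv(as.data.frame(curve), paths[["curve"]], row.names = FALSE,
            quote = FALSE)
  thr <- attr(curve, "threshold")
  rpt <- c(sprintf("layer=%s", layer),
           sprintf("direction=%s", attr(curve, "direction")),
           sprintf("n_draws=%d", attr(curve, "n_draws")),
           sprintf("n_excluded=%d", attr(curve, "n_excluded")),
           sprintf("threshold_openness_pct=%s",
                   if (is.na(thr)) "NA" else format(thr)))
  if (!is.null(summary)) {
    rpt <- c(rpt, "", "coefficients:",
             utils::capture.output(print(as.data.frame(summary),
                                         row.names = FALSE, digits = 4)))
  }
  writeLines(rpt, paths[["report"]])
  if (figure) {
    fig_path <- file.path(dir, paste0("severity_", layer, ".pdf"))
    p <- plot_severity(curve) +
      ggplot2::ggtitle(sprintf("Grazing severity, %s layer", layer))
    ggplot2::ggsave(fig_path, p, width = 6, height = 4)
    paths <- c(paths, figure = fig_path)
  }
  invisible(paths)
}

#' Plot a severity curve
#'
#' Posterior-mean ratio line with the 95% credible band and a reference
#' line at ratio 1; the detected threshold, if any, is marked.
#'
#' @param curve A [severity_curve()].
#' @param log_y Show the ratio on a log axis (ratios are multiplicative).
#' @return A ggplot object.
#' @export
plot_severity <- function(curve, log_y = TRUE) {
  df <- as.data.frame(curve)
  thr <- attr(curve, "threshold")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$openness_pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Canopy openness (%)",
                  y = "Occurrence-probability ratio (exclosure : grazing)") +
    ggplot2::theme_minimal()
  if (!is.na(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dotted")
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @importFrom ggplot2 .data
NULL
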