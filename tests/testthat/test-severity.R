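make_draws <- function(n, medians = table1_seedbank_medians, sd = 0) {
  # synthetic posterior: independent Normal perturbations around medians
  set.seed(80)
  draws <- sapply(names(medians), function(nm) rnorm(n, medians[[nm]], sd))
  if (n == 1) draws <- matrix(draws, nrow = 1,
                              dimnames = list(NULL, names(medians)))
  draws
}

test_that("the default openness grid has 49 integer points from 17 to 65", {
  g <- openness_grid()
  expect_equal(length(g), 49)
  expect_equal(g[1], 17)
  expect_equal(g[49], 65)
  expect_equal(unique(diff(g)), 1)
  expect_error(openness_grid(65, 17), "lower < upper")
  expect_error(openness_grid(step = 0), "step")
  expect_error(openness_grid(-3, 50), "\\[0, 100\\]")
})

test_that("plug-in probabilities match the direct arithmetic oracle", {
  medians <- table1_seedbank_medians
  # indicator-0 treatment at openness 65: logit^-1(-3.4 + 0.01*65)
  expect_equal(predict_probability(medians, "grazing", 65),
               1 / (1 + exp(3.4 - 0.01 * 65)), tolerance = 1e-12)
  expect_equal(predict_probability(medians, "grazing", 65), 0.0601,
               tolerance = 2e-3)
  # indicator-1 treatment: logit^-1(-3.4 + 1.95 + (0.01 - 0.07)*65)
  expect_equal(predict_probability(medians, "exclosure", 65),
               1 / (1 + exp(-(-1.45 - 0.06 * 65))), tolerance = 1e-12)
  expect_equal(predict_probability(medians, "exclosure", 65), 0.00473,
               tolerance = 1e-3)
  zero <- setNames(rep(0, 5), names(medians))
  for (op in c(17, 42, 65)) {
    expect_equal(predict_probability(zero, "exclosure", op), 0.5)
    expect_equal(predict_probability(zero, "grazing", op), 0.5)
  }
  expect_error(predict_probability(medians, "grazing", 120), "openness")
})

test_that("null treatment effects give a flat ratio of one and no threshold", {
  draws <- make_draws(200, sd = 0.3)
  draws[, "treatment"] <- 0
  draws[, "interaction"] <- 0
  curve <- severity_curve(draws)
  expect_equal(curve$mean_ratio, rep(1, 49))
  expect_equal(curve$ci_lo, rep(1, 49))
  expect_equal(curve$ci_hi, rep(1, 49))
  expect_true(is.na(attr(curve, "threshold")))
})

test_that("a single draw at the seed-bank medians crosses one at 1.95/0.07", {
  crossing <- 1.95 / 0.07  # where the treatment contrast vanishes
  one <- make_draws(1)
  curve <- severity_curve(one, grid = openness_grid())
  # exclosure-coded indicator: contrast positive below the crossing point
  expect_true(all(curve$mean_ratio[curve$openness_pct < crossing] > 1))
  expect_true(all(curve$mean_ratio[curve$openness_pct > crossing] < 1))
  # at the crossing itself the ratio is exactly one
  at <- severity_curve(one, grid = c(17, crossing, 65))
  expect_equal(at$mean_ratio[2], 1, tolerance = 1e-9)
  # degenerate posterior: mean ratio equals the single-draw ratio exactly
  p_ex <- predict_probability(one[1, ], "exclosure", 40)
  p_gr <- predict_probability(one[1, ], "grazing", 40)
  c40 <- severity_curve(one, grid = c(39, 40, 41))
  expect_equal(c40$mean_ratio[2], p_ex / p_gr, tolerance = 1e-12)
  expect_equal(c40$ci_lo[2], c40$ci_hi[2])
})

test_that("a dispersed posterior pushes the CI threshold past the crossing", {
  # under the grazing-marks-the-indicator reading the ratio rises with
  # openness; the CI lower bound must clear 1 later than the mean does
  draws <- make_draws(1000, sd = 0.02)
  curve <- severity_curve(draws, treatment_coding = "grazing_is_1")
  thr <- attr(curve, "threshold")
  expect_false(is.na(thr))
  expect_gt(thr, 1.95 / 0.07)
  # brute-force check of the reported band at the threshold point
  x <- thr
  eta_ex <- draws[, "intercept"] + draws[, "openness"] * x
  eta_gr <- draws[, "intercept"] + draws[, "treatment"] +
    (draws[, "openness"] + draws[, "interaction"]) * x
  ratio <- plogis(eta_ex) / plogis(eta_gr)
  expect_equal(curve$ci_lo[curve$openness_pct == x],
               quantile(ratio, 0.025, names = FALSE), tolerance = 1e-12)
  expect_gt(quantile(ratio, 0.025, names = FALSE), 1)
})

test_that("threshold detection is consistent with the credible band", {
  draws <- make_draws(1000, sd = 0.02)
  curve <- severity_curve(draws, treatment_coding = "grazing_is_1")
  thr <- attr(curve, "threshold")
  expect_true(all(curve$ci_lo[curve$openness_pct >= thr] > 1))
  before <- curve$ci_lo[curve$openness_pct == thr - 1]
  expect_lte(before, 1)
  expect_true(all(curve$ci_lo <= curve$mean_ratio + 1e-12))
  expect_true(all(curve$ci_hi >= curve$ci_lo))
})

test_that("swapping the ratio direction maps the band to its reciprocal", {
  draws <- make_draws(5000, sd = 0.05)
  up <- severity_curve(draws)
  down <- severity_curve(draws, direction = "grazing_over_exclosure")
  # per-draw ratios are exact reciprocals, so the mean of the swapped
  # direction is the mean reciprocal and quantiles mirror (up to the
  # interpolation between adjacent order statistics)
  x <- 40
  eta_ex <- draws[, "intercept"] + draws[, "treatment"] +
    (draws[, "openness"] + draws[, "interaction"]) * x
  eta_gr <- draws[, "intercept"] + draws[, "openness"] * x
  r <- plogis(eta_ex) / plogis(eta_gr)
  i <- which(up$openness_pct == x)
  expect_equal(down$mean_ratio[i], mean(1 / r), tolerance = 1e-12)
  # quantiles mirror up to the linear interpolation between adjacent order
  # statistics, which shrinks with the number of draws
  expect_equal(down$ci_lo[i], 1 / up$ci_hi[i], tolerance = 0.01)
  expect_equal(down$ci_hi[i], 1 / up$ci_lo[i], tolerance = 0.01)
})

test_that("widening the posterior spread never narrows the credible band", {
  draws <- make_draws(800, sd = 0.03)
  center <- colMeans(draws)
  wide <- sweep(sweep(draws, 2, center), 2, rep(2, 5), `*`)
  wide <- sweep(wide, 2, center, `+`)
  colnames(wide) <- colnames(draws)
  c1 <- severity_curve(draws)
  c2 <- severity_curve(wide)
  expect_true(all(c2$ci_hi - c2$ci_lo >= c1$ci_hi - c1$ci_lo - 1e-9))
})

test_that("underflowed denominators are excluded and counted", {
  draws <- make_draws(10, sd = 0)
  draws[1, "intercept"] <- -800  # grazing-side probability underflows to 0
  expect_message(curve <- severity_curve(draws), "excluded")
  expect_equal(attr(curve, "n_excluded"), 49)  # one draw at all 49 points
  expect_true(all(is.finite(curve$mean_ratio)))
})

test_that("curve reports write the grid, threshold and figures", {
  dir <- withr::local_tempdir()
  draws <- make_draws(200, sd = 0.02)
  curve <- severity_curve(draws, treatment_coding = "grazing_is_1")
  paths <- curve_report(curve, dir, layer = "seedbank")
  expect_true(all(file.exists(paths)))
  tab <- read.csv(paths[["curve"]])
  expect_equal(nrow(tab), 49)
  expect_equal(names(tab), c("openness_pct", "mean_ratio", "ci_lo", "ci_hi"))
  rpt <- readLines(paths[["report"]])
  expect_true(any(grepl("threshold_openness_pct=", rpt)))

  # a flat all-ones curve reports no threshold
  flat <- make_draws(50, sd = 0)
  flat[, "treatment"] <- 0
  flat[, "interaction"] <- 0
  fc <- severity_curve(flat)
  p2 <- curve_report(fc, dir, layer = "aboveground", figure = FALSE)
  expect_true(any(grepl("threshold_openness_pct=NA",
                        readLines(p2[["report"]]))))
  # per-layer suffixes keep the two layers apart
  expect_true(file.exists(file.path(dir, "severity_seedbank.csv")))
  expect_true(file.exists(file.path(dir, "severity_aboveground.csv")))
})
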