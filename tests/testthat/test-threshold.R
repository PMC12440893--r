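test_that("locally linear smoothing reproduces affine data exactly", {
  set.seed(2)
  x <- sort(runif(80, 0, 10))
  y <- 2 * x - 4
  for (span in c(0.2, 0.3, 0.7, 1)) {
    cv <- lowess_fit(x, y, span = span, grid_n = 50)
    expect_equal(cv$fitted_y, 2 * cv$grid_x - 4, tolerance = 1e-12)
  }
  # constant data reproduced exactly
  cv0 <- lowess_fit(x, rep(3.5, 80), span = 0.3)
  expect_equal(cv0$fitted_y, rep(3.5, 200))
  # the crossing of an affine trend is recovered to machine precision
  cvl <- lowess_fit(x, 5 * (x - 6.321), span = 0.3)
  expect_equal(zero_crossings(cvl)$x, 6.321, tolerance = 1e-10)
})

test_that("every grid evaluation matches the brute-force weighted solve", {
  set.seed(31)
  x <- runif(50, -2, 5)
  y <- sin(x) + rnorm(50, 0, 0.3)
  grid <- seq(min(x), max(x), length.out = 37)
  cv <- lowess_fit(x, y, span = 0.3, grid_x = grid)
  for (i in seq_along(grid)) {
    expect_equal(cv$fitted_y[i], lowess_oracle_point(x, y, grid[i], 0.3),
                 tolerance = 1e-9)
  }
  # and for a second span
  cv2 <- lowess_fit(x, y, span = 0.6, grid_x = grid)
  oracle2 <- vapply(grid, function(g) lowess_oracle_point(x, y, g, 0.6),
                    numeric(1))
  expect_equal(cv2$fitted_y, oracle2, tolerance = 1e-9)
})

test_that("degenerate local designs are refused or fall back gracefully", {
  expect_error(lowess_fit(1:4, 1:4, span = 0.5), "n >= 5")
  # all neighbours at one x: weighted-mean fallback with a warning
  x <- c(rep(2, 8), 9, 9.5)
  y <- c(rnorm(8, 1, 0.01), 5, 6)
  expect_warning(cv <- lowess_fit(x, y, span = 0.5, grid_x = c(2)),
                 "singular local design")
  expect_equal(cv$fitted_y, mean(y[1:8]), tolerance = 0.02)
})

test_that("zero crossings are located, directed and ordered", {
  line <- lowess_fit(seq(0, 4, length.out = 20), seq(0, 4, length.out = 20) - 2,
                     span = 1, grid_x = seq(0, 4, length.out = 9))
  cr <- zero_crossings(line)
  expect_equal(nrow(cr), 1)
  expect_equal(cr$x, 2)
  expect_equal(cr$direction, "-+")

  pos <- list(grid_x = 1:5, fitted_y = c(1, 2, 1, 3, 2))
  expect_equal(nrow(zero_crossings(pos)), 0)

  # cubic-shaped curve with three sign changes: crossings match the
  # roots of the dense linear interpolant
  g <- seq(-2, 2, length.out = 401)
  fy <- (g - 1) * g * (g + 1.5)
  cr3 <- zero_crossings(list(grid_x = g, fitted_y = fy))
  expect_equal(nrow(cr3), 3)
  expect_equal(cr3$x, c(-1.5, 0, 1), tolerance = 1e-4)
  expect_equal(cr3$direction, c("-+", "+-", "-+"))
  expect_false(is.unsorted(cr3$x))
})

test_that("noiseless linear data give a zero-width bootstrap interval", {
  set.seed(4)
  pairs <- data.frame(x = runif(60, 0, 10))
  pairs$phi <- 1.5 * (pairs$x - 4)
  thr <- bootstrap_threshold(pairs, span = 0.4, n_boot = 50, seed = 1)
  expect_equal(thr$point, 4, tolerance = 1e-10)
  expect_equal(thr$ci_low, 4, tolerance = 1e-8)
  expect_equal(thr$ci_high, 4, tolerance = 1e-8)
  expect_equal(thr$unstable_fraction, 0)
  # same seed, same interval
  thr2 <- bootstrap_threshold(pairs, span = 0.4, n_boot = 50, seed = 1)
  expect_identical(thr$boot_points, thr2$boot_points)
  expect_error(bootstrap_threshold(data.frame(x = 1:50, phi = rep(1, 50))),
               "never crosses")
})

test_that("resamples without a matching crossing are counted and flagged", {
  set.seed(9)
  # weak signal drowned in noise: many resamples lose the crossing
  pairs <- data.frame(x = runif(40, 0, 1))
  pairs$phi <- 0.02 * (pairs$x - 0.5) + rnorm(40, 0.03, 0.05)
  full <- lowess_fit(pairs$x, pairs$phi, span = 0.5)
  cr <- zero_crossings(full)
  if (nrow(cr) > 0) {
    thr <- suppressWarnings(
      bootstrap_threshold(pairs, span = 0.5, n_boot = 100, seed = 2))
    expect_gte(thr$unstable_fraction, 0)
    expect_identical(thr$unstable, thr$unstable_fraction > 0.5)
  }
  succeed()
})

test_that("plateau detection finds the earliest flat tail", {
  g <- seq(0, 10, length.out = 101)
  # rises to 6 then flat
  curve <- list(grid_x = g, fitted_y = pmin(g, 6))
  pl <- detect_plateau(curve, slope_tolerance = 1e-8)
  expect_equal(pl$start, 6, tolerance = 0.11)
  # strictly increasing line with slope above tolerance: no plateau
  expect_null(detect_plateau(list(grid_x = g, fitted_y = 2 * g),
                             slope_tolerance = 0.5))
  # constant curve: plateau from the first grid point
  expect_equal(detect_plateau(list(grid_x = g, fitted_y = rep(1, 101)),
                              slope_tolerance = 1e-12)$start, 0)
})

test_that("a planted plateau effect is localised through the full pipeline", {
  ranges <- key_ranges()
  pl <- effect_spec("PD", "plateau", plateau_start = 1250, slope_below = 1)
  pl <- settlehealth:::scale_effect_to_sd(pl, ranges$PD[1], ranges$PD[2], 0.08)
  spec <- synthetic_spec(ranges, list(pl), noise_sd = 0.01, intercept = 0.6,
                         seed = 15)
  gp <- generate_panel(spec)
  m <- hse_model(recovery_formula(), gp$panel, family = "xgboost", seed = 1)
  A <- compute_attributions(m, gp$panel)
  sc <- attribution_scatter(A, "PD")
  cv <- lowess_fit(sc$x, sc$phi, span = 0.3)
  found <- detect_plateau(cv, slope_tolerance = 1e-5)
  expect_false(is.null(found))
  # within ~10% of the feature range of the planted plateau start
  expect_lt(abs(found$start - 1250), 0.12 * diff(ranges$PD))
})

test_that("bootstrap threshold recovers a planted breakpoint end to end", {
  b <- 57
  gp <- generate_panel(scenario_recovery(seed = 101, b = b))
  m <- hse_model(recovery_formula(), gp$panel, family = "xgboost", seed = 2025)
  A <- compute_attributions(m, gp$panel)
  sc <- attribution_scatter(A, "UR")
  thr <- bootstrap_threshold(sc, span = 0.3, n_boot = 200, seed = 101,
                             recenter = TRUE)
  expect_equal(thr$direction, "-+")
  expect_lt(abs(thr$point - b), 0.1 * diff(key_ranges()$UR))
  expect_lte(thr$ci_low, thr$point)
  expect_gte(thr$ci_high, thr$point)
})
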