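test_that("effect shapes are evaluated correctly and continuously", {
  lin <- effect_spec("f", "linear", slope = 2)
  expect_equal(evaluate_effect(lin, 3), 6)

  pw <- effect_spec("f", "piecewise", breakpoint = 5,
                    slope_below = -1, slope_above = 1)
  # continuity at the breakpoint: both one-sided branches agree
  expect_equal(evaluate_effect(pw, 5), -1 * (5 - 5))
  expect_equal(evaluate_effect(pw, 5), 1 * (5 - 5))
  eps <- 1e-9
  expect_equal(evaluate_effect(pw, 5 - eps), evaluate_effect(pw, 5 + eps),
               tolerance = 1e-7)

  pl <- effect_spec("f", "plateau", plateau_start = 10, slope_below = 2)
  expect_equal(evaluate_effect(pl, 12), evaluate_effect(pl, 15))
  expect_equal(evaluate_effect(pl, 10 - eps), evaluate_effect(pl, 10 + eps),
               tolerance = 1e-7)

  # continuity everywhere, on a dense sweep over all three shapes
  g <- seq(0, 20, length.out = 4001)
  for (e in list(lin, pw, pl)) {
    y <- evaluate_effect(e, g)
    expect_true(max(abs(diff(y))) < 0.05)
  }

  bad <- effect_spec("f", "linear", slope = 1)
  bad$shape <- "mystery"
  expect_error(evaluate_effect(bad, 1), "unknown effect shape")
})

test_that("spec validation rejects malformed generating conditions", {
  r <- list(a = c(0, 1))
  e <- list(effect_spec("a", "linear", slope = 1))
  expect_error(synthetic_spec(r, list()), "non-empty")
  expect_error(synthetic_spec(r, list(effect_spec("zz", "linear", slope = 1))),
               "unknown feature")
  expect_error(synthetic_spec(r, e, noise_sd = -1))
  expect_error(synthetic_spec(list(a = c(1, 0)), e), "min < max")
  expect_error(
    synthetic_spec(r, list(effect_spec("a", "piecewise", breakpoint = 2,
                                       slope_below = 1, slope_above = 2))),
    "inside its generating range")
})

test_that("panel generation is seed-deterministic and noise-free when asked", {
  spec <- scenario_recovery(seed = 7)
  g1 <- generate_panel(spec)
  g2 <- generate_panel(spec)
  expect_identical(g1$panel, g2$panel)
  expect_identical(g1$true_index, g2$true_index)
  expect_equal(nrow(g1$panel), spec$n_units * spec$n_periods)

  spec0 <- scenario_recovery(seed = 7, noise_sd = 0)
  g0 <- generate_panel(spec0)
  expect_equal(g0$panel$HLI, g0$true_index)

  # features stay inside their declared ranges
  for (nm in names(spec$feature_ranges)) {
    r <- spec$feature_ranges[[nm]]
    expect_true(all(g1$panel[[nm]] >= r[1] & g1$panel[[nm]] <= r[2]))
  }
})

test_that("with a single noiseless effect the outcome is an exact function of its feature", {
  r <- list(x1 = c(0, 10), x2 = c(0, 10))
  e <- effect_spec("x1", "piecewise", breakpoint = 4,
                   slope_below = 1, slope_above = 3)
  spec <- synthetic_spec(r, list(e), noise_sd = 0, seed = 3)
  gp <- generate_panel(spec)
  expect_equal(gp$panel$HLI, evaluate_effect(e, gp$panel$x1))
})

test_that("a least-squares breakpoint scan recovers the planted kink", {
  # single piecewise effect, small noise; oracle: continuous hinge
  # regression over a candidate-breakpoint grid
  b_true <- 57
  ranges <- key_ranges()
  eff <- effect_spec("UR", "piecewise", breakpoint = b_true,
                     slope_below = 0.001, slope_above = 0.004)
  spec <- synthetic_spec(ranges, list(eff), noise_sd = 0.005,
                         intercept = 0.6, seed = 11)
  gp <- generate_panel(spec)
  x <- gp$panel$UR; y <- gp$panel$HLI
  cand <- seq(40, 75, by = 0.25)
  rss <- vapply(cand, function(b) {
    lo <- pmin(x - b, 0); hi <- pmax(x - b, 0)
    sum(stats::lm(y ~ lo + hi)$residuals^2)
  }, numeric(1))
  expect_lt(abs(cand[which.min(rss)] - b_true), 1.5)
})

test_that("gaussian-copula correlation knob induces the requested dependence", {
  r <- list(a = c(0, 1), b = c(0, 1), c = c(0, 1))
  e <- list(effect_spec("a", "linear", slope = 1))
  spec <- synthetic_spec(r, e, noise_sd = 0, seed = 5, copula_corr = 0.7,
                         n_units = 50, n_periods = 10)
  gp <- generate_panel(spec)
  C <- cor(as.matrix(gp$panel[, c("a", "b", "c")]))
  off <- C[upper.tri(C)]
  expect_true(all(off > 0.5 & off < 0.8))
})

test_that("health indicators follow the latent score with declared directions", {
  spec <- scenario_recovery(seed = 13)
  gp <- generate_panel(spec)
  ind <- generate_health_indicators(gp, indicator_noise = 0)
  latent <- attr(ind, "latent")
  dirs <- health_indicator_directions()
  expect_setequal(names(dirs), c("incidence_ab", "mortality_ab",
                                 "human_mortality", "life_expectancy"))
  # perfect rank alignment at zero noise, after sign flips for negatives
  for (nm in names(dirs)) {
    s <- if (dirs[[nm]] == "negative") -1 else 1
    expect_equal(cor(s * ind[[nm]], latent, method = "spearman"), 1)
  }
  # indicators are deterministic functions of the latent score at zero
  # noise: equal scores would give equal rows (affine construction)
  z <- (latent - min(latent)) / diff(range(latent))
  expect_equal(ind$life_expectancy, 72 + 8 * z)

  # reproducible under the same spec
  ind_b <- generate_health_indicators(generate_panel(spec), indicator_noise = 0)
  expect_identical(ind[names(dirs)], ind_b[names(dirs)])
})

test_that("latent health ranking survives the composite-index construction", {
  spec <- scenario_recovery(seed = 17)
  gp <- generate_panel(spec)
  ind <- generate_health_indicators(gp, indicator_noise = 0.01)
  h <- suppressWarnings(build_hli(ind))
  rho <- cor(attr(ind, "latent"), h$closeness, method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("panels round-trip through CSV", {
  spec <- scenario_recovery(seed = 19)
  gp <- generate_panel(spec)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_panel_csv(gp$panel, path)
  back <- read_panel_csv(path)
  expect_equal(names(back), names(gp$panel))
  expect_equal(back$HLI, gp$panel$HLI, tolerance = 1e-12)
})
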