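test_that("derived settlement indicators are the expected ratios", {
  raw <- data.frame(road_area = c(6e6, 2e6),
                    resident_pop_year_end = c(1e6, 5e5),
                    sanitation_vehicles = c(200, 40),
                    admin_area = c(1e5, 2e4),
                    urban_pop = c(650000, 100000))
  d <- derive_indicators(raw)
  expect_equal(d$RAPC, c(6, 4))
  expect_equal(d$NSV, c(2, 0.8))
  expect_equal(d$PD, c(10, 25))
  expect_equal(d$UR, c(65, 20))
  raw$resident_pop_year_end[2] <- 0
  expect_error(derive_indicators(raw), "rows: 2")
})

test_that("interior gaps interpolate linearly; edge gaps are refused", {
  yrs <- 2010:2015
  v <- c(74, NA, NA, NA, NA, 76.5)
  out <- interpolate_series(yrs, v)
  expect_equal(out[3], 75)                       # 2012
  expect_equal(out, seq(74, 76.5, by = 0.5))
  # closed-form straight line over a decade
  yrs2 <- 2010:2020
  v2 <- c(70, rep(NA, 9), 80)
  expect_equal(interpolate_series(yrs2, v2), 70:80)
  # anchors untouched, identity when no gaps
  full <- c(1, 4, 2, 8)
  expect_identical(interpolate_series(2011:2014, full), full)
  expect_error(interpolate_series(yrs, c(NA, 74, 75, NA, 76, 77)),
               "interior interpolation only")
  expect_error(interpolate_series(yrs, c(rep(NA, 5), 76)), "2 observed")
})

test_that("correlation screen flags strong pairs and rejects constants", {
  set.seed(1)
  X <- cbind(a = rnorm(1000), b = rnorm(1000))
  sc <- correlation_screen(X)
  expect_equal(diag(sc$correlations), c(a = 1, b = 1))
  expect_lt(abs(sc$correlations["a", "b"]), 0.2)
  expect_equal(nrow(sc$flagged), 0)

  Y <- cbind(x = 1:10, y = -(1:10))
  expect_warning(sc2 <- correlation_screen(Y, limit = 0.6), "1 indicator pair")
  expect_equal(sc2$correlations["x", "y"], -1)
  expect_equal(nrow(sc2$flagged), 1)

  expect_error(correlation_screen(cbind(k = rep(1, 5), z = 1:5)), "constant")
})

test_that("direction-aware normalisation maps extrema as declared", {
  X <- cbind(p = c(2, 4, 6), n = c(2, 4, 6))
  dirs <- c(p = "positive", n = "negative")
  Xn <- normalize_decision(X, dirs)
  expect_equal(Xn[, "p"], c(0, 0.5, 1))
  expect_equal(Xn[, "n"], c(1, 0.5, 0))
  # negating a column and flipping its tag gives the same normalisation
  X2 <- cbind(p = c(2, 4, 6), n = -c(2, 4, 6))
  Xn2 <- normalize_decision(X2, c(p = "positive", n = "positive"))
  expect_equal(Xn2, Xn)
  expect_error(normalize_decision(cbind(q = 1:3), dirs), "direction tag")
})

test_that("entropy weights match the hand-evaluated formulas", {
  # permuted columns share a weight of one half
  X <- cbind(a = c(1, 0, 1), b = c(0, 1, 1))
  ew <- entropy_weights(X)
  expect_equal(unname(ew$weights), c(0.5, 0.5))
  # hand evaluation: r_a = (1/2, 0, 1/2), e = ln2/ln3 for both columns
  expect_equal(unname(ew$entropy), rep(log(2) / log(3), 2))
  # constant positive column: maximal entropy, zero weight
  Y <- cbind(c1 = c(0.5, 0.5, 0.5), c2 = c(0, 0.5, 1))
  ewy <- entropy_weights(Y)
  expect_equal(unname(ewy$entropy[1]), 1)
  expect_equal(unname(ewy$weights[1]), 0)
  expect_error(entropy_weights(cbind(a = rep(1, 4))), "degenerate")
})

test_that("TOPSIS closeness matches a hand-worked example and its bounds", {
  Xn <- rbind(c(1, 0.2), c(0, 1), c(0.4, 0.6))
  tp <- topsis_closeness(Xn, c(0.5, 0.5))
  # hand evaluation: V = Xn/2, S+ = (.5,.5), S- = (0,.1)
  d1p <- sqrt(0 + 0.16); d1m <- sqrt(0.25 + 0)
  d2p <- sqrt(0.25 + 0); d2m <- sqrt(0 + 0.16)
  d3p <- sqrt(0.09 + 0.04); d3m <- sqrt(0.04 + 0.04)
  expect_equal(tp$closeness,
               c(d1m / (d1p + d1m), d2m / (d2p + d2m), d3m / (d3p + d3m)))
  # column-wise best scores 1, worst scores 0
  Z <- rbind(c(1, 1), c(0, 0), c(0.3, 0.8))
  tz <- topsis_closeness(Z, c(0.4, 0.6))
  expect_equal(tz$closeness[1], 1)
  expect_equal(tz$closeness[2], 0)
  # identical rows get identical closeness
  W <- rbind(c(0.2, 0.7), c(0.2, 0.7), c(1, 0), c(0, 1))
  tw <- topsis_closeness(W, c(0.5, 0.5))
  expect_equal(tw$closeness[1], tw$closeness[2])
})

test_that("composite index matches the independent plain-loop oracle on small matrices", {
  for (fx in topsis_fixtures()) {
    dirs <- stats::setNames(fx$dir, colnames(fx$X))
    h <- build_hli(as.data.frame(fx$X), dirs, column = "idx")
    orc <- topsis_oracle(fx$X, fx$dir)
    expect_equal(unname(h$weights), orc$weights, tolerance = 1e-12)
    expect_equal(unname(h$closeness), orc$hli, tolerance = 1e-12)
    expect_equal(sum(h$weights), 1, tolerance = 1e-12)
    expect_true(all(h$closeness >= 0 & h$closeness <= 1))
  }
})

test_that("index is invariant to positive affine rescaling of raw columns", {
  fx <- topsis_fixtures()[[2]]
  dirs <- stats::setNames(fx$dir, colnames(fx$X))
  h0 <- build_hli(as.data.frame(fx$X), dirs)
  X2 <- fx$X
  X2[, 1] <- 3.7 * X2[, 1] + 11
  X2[, 4] <- 0.2 * X2[, 4] - 5
  h2 <- build_hli(as.data.frame(X2), dirs)
  expect_equal(h2$closeness, h0$closeness, tolerance = 1e-12)
  expect_equal(h2$weights, h0$weights, tolerance = 1e-12)
})

test_that("index is invariant to negating a column while flipping its tag", {
  fx <- topsis_fixtures()[[1]]
  dirs <- stats::setNames(fx$dir, colnames(fx$X))
  h0 <- build_hli(as.data.frame(fx$X), dirs)
  X2 <- fx$X; X2[, 2] <- -X2[, 2]
  dirs2 <- dirs
  dirs2[2] <- if (dirs[2] == "negative") "positive" else "negative"
  h2 <- build_hli(as.data.frame(X2), dirs2)
  expect_equal(h2$closeness, h0$closeness, tolerance = 1e-12)
  expect_equal(unname(h2$weights), unname(h0$weights), tolerance = 1e-12)
})

test_that("duplicating every row leaves per-row index values unchanged", {
  fx <- topsis_fixtures()[[2]]
  dirs <- stats::setNames(fx$dir, colnames(fx$X))
  h0 <- build_hli(as.data.frame(fx$X), dirs)
  dup <- as.data.frame(fx$X[rep(seq_len(nrow(fx$X)), each = 2), ])
  h2 <- build_hli(dup, dirs)
  expect_equal(h2$closeness[seq(1, nrow(dup), by = 2)], h0$closeness,
               tolerance = 1e-12)
  expect_equal(h2$weights, h0$weights, tolerance = 1e-12)
})

test_that("noiseless monotone indicators reproduce the latent ranking exactly", {
  spec <- scenario_recovery(seed = 23)
  ind <- generate_health_indicators(generate_panel(spec), indicator_noise = 0)
  h <- suppressWarnings(build_hli(ind))
  expect_equal(order(h$closeness), order(attr(ind, "latent")))
})
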