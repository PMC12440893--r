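# Shared study conditions and toy models for the test suite.

key_ranges <- function() {
  list(NMIB = c(27.15, 84.31), UR = c(22.86, 89.58), MPPR = c(57.3, 189.46),
       RAPC = c(1.14, 13.71), PD = c(2.57, 3925.87), UGPR = c(29.79, 100))
}

# V-shaped effect: near-zero linear component, strong nonlinearity.
vshape_effect <- function(feature, b, ranges, target_sd) {
  e <- effect_spec(feature, "piecewise", breakpoint = b,
                   slope_below = -1, slope_above = 1)
  settlehealth:::scale_effect_to_sd(e, ranges[[feature]][1],
                                    ranges[[feature]][2], target_sd)
}

# Strongly nonlinear panel: V-shaped kinks plus a plateau; a linear
# baseline has almost nothing to work with here.
scenario_nonlinear <- function(seed = 42L, noise_sd = 0.03) {
  ranges <- key_ranges()
  plateau <- effect_spec("PD", "plateau", plateau_start = 1250,
                         slope_below = 1 / 1000)
  plateau <- settlehealth:::scale_effect_to_sd(plateau, ranges$PD[1],
                                               ranges$PD[2], 0.04)
  effects <- list(vshape_effect("NMIB", 56, ranges, 0.06),
                  vshape_effect("UR", 56, ranges, 0.05),
                  vshape_effect("MPPR", 123, ranges, 0.05),
                  vshape_effect("RAPC", 7, ranges, 0.04),
                  plateau)
  synthetic_spec(ranges, effects, noise_sd = noise_sd, intercept = 0.6,
                 seed = seed)
}

# Breakpoint-recovery conditions: one mean-zero sign-changing piecewise
# effect on UR with the kink near the range midpoint (51% of the range,
# inside the central 60%), two mild linear nuisance effects, three pure
# noise features; signal sd ~0.085 against noise sd 0.03 (SNR ~ 2.8).
scenario_recovery <- function(seed = 1L, b = 57, noise_sd = 0.03) {
  ranges <- key_ranges()
  effects <- list(
    piecewise_effect_meanzero("UR", b, ranges$UR[1], ranges$UR[2], 0.08,
                              sign = +1),
    effect_spec("MPPR", "linear", slope = 0.02 / (diff(ranges$MPPR) / sqrt(12))),
    effect_spec("RAPC", "linear", slope = 0.02 / (diff(ranges$RAPC) / sqrt(12))))
  synthetic_spec(ranges, effects, noise_sd = noise_sd, intercept = 0.6,
                 seed = seed)
}

recovery_formula <- function() HLI ~ NMIB + UR + MPPR + RAPC + PD + UGPR

# Deterministic toy models with a registered predict method, for the
# attribution and partial-dependence stages.
toy_model <- function(f) structure(list(f = f), class = "toy_model")
predict.toy_model <- function(object, newdata, ...) object$f(newdata)
registerS3method("predict", "toy_model", predict.toy_model,
                 envir = asNamespace("stats"))

# Independent Entropy-TOPSIS oracle: plain-loop evaluation of the
# normalisation, entropy-weighting and closeness formulas, step by step.
topsis_oracle <- function(X, directions) {
  m <- nrow(X); p <- ncol(X)
  Xn <- matrix(0, m, p)
  for (j in seq_len(p)) {
    lo <- min(X[, j]); hi <- max(X[, j])
    for (i in seq_len(m)) {
      Xn[i, j] <- if (hi == lo) 0
      else if (directions[j] == "positive") (X[i, j] - lo) / (hi - lo)
      else (hi - X[i, j]) / (hi - lo)
    }
  }
  e <- numeric(p)
  for (j in seq_len(p)) {
    s <- sum(Xn[, j])
    if (s == 0) { e[j] <- 1; next }
    acc <- 0
    for (i in seq_len(m)) {
      r <- Xn[i, j] / s
      if (r > 0) acc <- acc + r * log(r)
    }
    e[j] <- -acc / log(m)
  }
  d <- 1 - e
  w <- d / sum(d)
  V <- matrix(0, m, p)
  for (j in seq_len(p)) for (i in seq_len(m)) V[i, j] <- w[j] * Xn[i, j]
  splus <- apply(V, 2, max); sminus <- apply(V, 2, min)
  hli <- numeric(m)
  for (i in seq_len(m)) {
    dp <- sqrt(sum((V[i, ] - splus)^2))
    dm <- sqrt(sum((V[i, ] - sminus)^2))
    hli[i] <- dm / (dp + dm)
  }
  list(weights = w, entropy = e, hli = hli)
}

# Fixture set of small decision matrices (<= 5 samples x 4 indicators).
topsis_fixtures <- function() {
  set.seed(99)
  fx <- list(
    list(X = matrix(c(1, 2, 3, 4,
                      4, 3, 2, 1,
                      2, 2, 5, 1), nrow = 3, byrow = TRUE),
         dir = c("positive", "negative", "positive", "negative")),
    list(X = matrix(c(10, 0.2, 7, 74,
                      30, 0.9, 9, 70,
                      20, 0.5, 8, 72,
                      15, 0.3, 6, 76,
                      25, 0.7, 5, 71), nrow = 5, byrow = TRUE),
         dir = c("negative", "negative", "negative", "positive")),
    list(X = matrix(runif(16), nrow = 4),
         dir = c("positive", "positive", "negative", "positive")),
    list(X = matrix(c(rexp(10), rnorm(10, 50, 5)), nrow = 5),
         dir = c("negative", "positive", "positive", "negative")))
  for (i in seq_along(fx)) colnames(fx[[i]]$X) <- paste0("I", 1:4)
  fx
}

# Brute-force tricube local-linear fit at one grid point, via stats::lm.
lowess_oracle_point <- function(x, y, g, span) {
  n <- length(x)
  k <- ceiling(span * n)
  d <- abs(x - g)
  radius <- sort(d)[k]
  keep <- d <= radius
  df <- data.frame(xx = x[keep], yy = y[keep],
                   ww = (1 - pmin(d[keep] / radius, 1)^3)^3)
  fit <- stats::lm(yy ~ xx, data = df, weights = ww)
  unname(stats::predict(fit, newdata = data.frame(xx = g))[1])
}
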