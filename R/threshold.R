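#' Locally linear LOWESS fit on a grid
#'
#' At every grid point, fits a degree-1 weighted least squares line over
#' the \code{ceiling(span * n)} nearest data points, with tricube
#' weights on distance scaled by the neighbourhood radius, and reports
#' the fitted value. The local fit is solved exactly, so affine data are
#' reproduced exactly for any span. When all neighbours share one x
#' value the local design is singular and the fit falls back to their
#' weighted mean with a warning.
#'
#' @param x,y numeric data vectors (n >= 5 and at least 3 neighbours per
#'   fit).
#' @param span fraction of points in each local fit, in (0, 1]
#'   (default 0.3).
#' @param grid_x evaluation points; default \code{grid_n} equally spaced
#'   points spanning the range of \code{x}.
#' @param grid_n grid resolution when \code{grid_x} is not given
#'   (default 200).
#' @return object of class \code{"lowess_curve"}: list with
#'   \code{grid_x} (strictly increasing), \code{fitted_y}, \code{span},
#'   \code{degree} (always 1), \code{n}.
#' @export
lowess_fit <- function(x, y, span = 0.3, grid_x = NULL, grid_n = 200L) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)),
            span > 0, span <= 1)
  n <- length(x)
  k <- ceiling(span * n)
  if (n < 5L || k < 3L)
    stop("need n >= 5 and at least 3 points per local fit (ceiling(span*n) >= 3)")
  if (is.null(grid_x)) grid_x <- seq(min(x), max(x), length.out = grid_n)
  stopifnot(!is.unsorted(grid_x, strictly = TRUE))
  g <- length(grid_x)
  # distances grid x data, k-nearest neighbourhood radius per grid point
  D <- abs(outer(grid_x, x, "-"))
  radius <- apply(D, 1L, function(r) sort(r, partial = k)[k])
  W <- (1 - pmin(D / pmax(radius, .Machine$double.xmin), 1)^3)^3
  W[D > radius] <- 0
  # zero radius: >= k points exactly at the grid point; weight them equally
  zr <- radius == 0
  if (any(zr)) W[zr, ] <- (D[zr, , drop = FALSE] == 0) * 1
  Xc <- matrix(x, g, n, byrow = TRUE)
  Yc <- matrix(y, g, n, byrow = TRUE)
  s0 <- rowSums(W); s1 <- rowSums(W * Xc); s2 <- rowSums(W * Xc^2)
  t0 <- rowSums(W * Yc); t1 <- rowSums(W * Xc * Yc)
  det <- s0 * s2 - s1^2
  singular <- det <= .Machine$double.eps * pmax(s0 * s2, s1^2, 1)
  fitted_y <- numeric(g)
  ok <- !singular
  beta <- (s0[ok] * t1[ok] - s1[ok] * t0[ok]) / det[ok]
  alpha <- (t0[ok] - beta * s1[ok]) / s0[ok]
  fitted_y[ok] <- alpha + beta * grid_x[ok]
  if (any(singular)) {
    warning("singular local design at ", sum(singular),
            " grid point(s); falling back to the weighted mean")
    fitted_y[singular] <- t0[singular] / s0[singular]
  }
  structure(list(grid_x = grid_x, fitted_y = fitted_y, span = span,
                 degree = 1L, n = n, k = k),
            class = "lowess_curve")
}

#' @export
print.lowess_curve <- function(x, ...) {
  cat("LOWESS curve: span", x$span, "(", x$k, "of", x$n, "points per fit ),",
      length(x$grid_x), "grid points\n")
  invisible(x)
}

#' Zero crossings of a smoothed curve
#'
#' Scans adjacent grid points for sign changes of the fitted values and
#' locates each crossing by linear interpolation; an exact zero at a
#' grid point is reported once. Crossings are ordered by x.
#'
#' @param curve a [lowess_fit()] result (or any list with \code{grid_x}
#'   and \code{fitted_y}).
#' @return data frame with columns \code{x} (crossing location) and
#'   \code{direction} (\code{"-+"} rising through zero or \code{"+-"}
#'   falling); zero rows when the curve never crosses.
#' @export
zero_crossings <- function(curve) {
  gx <- curve$grid_x; fy <- curve$fitted_y
  stopifnot(length(gx) == length(fy), length(gx) >= 2L)
  xs <- numeric(0); dir <- character(0)
  i <- 1L
  while (i < length(gx)) {
    a <- fy[i]; b <- fy[i + 1L]
    if (a == 0) {
      # exact grid zero: direction from the surrounding signs
      before <- if (i > 1L) fy[i - 1L] else -b
      if (sign(before) != sign(b) && b != 0) {
        xs <- c(xs, gx[i]); dir <- c(dir, if (b > 0) "-+" else "+-")
      }
    } else if (b != 0 && sign(a) != sign(b)) {
      xc <- gx[i] + (0 - a) / (b - a) * (gx[i + 1L] - gx[i])
      xs <- c(xs, xc); dir <- c(dir, if (b > 0) "-+" else "+-")
    }
    i <- i + 1L
  }
  if (length(gx) >= 2L && fy[length(fy)] == 0 && fy[length(fy) - 1L] != 0) {
    xs <- c(xs, gx[length(gx)])
    dir <- c(dir, if (fy[length(fy) - 1L] < 0) "-+" else "+-")
  }
  data.frame(x = xs, direction = dir)
}

#' Bootstrap percentile confidence interval for a threshold
#'
#' Estimates the feature value at which the smoothed attribution curve
#' crosses zero, with a 95 percent percentile confidence interval from
#' resampling the (x, attribution) pairs with replacement, refitting the
#' LOWESS curve on each resample, and recording the crossing matched to
#' the full-data crossing (nearest in x among crossings of the same
#' direction). Resamples with no matching crossing are counted and
#' reported; more than half missing flags the estimate unstable.
#'
#' @param pairs data frame with columns \code{x} and \code{phi} (as from
#'   [attribution_scatter()]).
#' @param span LOWESS span (default 0.3).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed; identical seeds reproduce the interval
#'   exactly.
#' @param level confidence level (default 0.95).
#' @param grid_n grid resolution for each fit.
#' @param which_crossing index (after ordering by x) or \code{"first"} /
#'   \code{"last"} selecting the headline crossing when the full-data
#'   curve crosses more than once; all crossings are returned alongside.
#' @param recenter when \code{TRUE}, each resample's attributions are
#'   shifted to mean zero before smoothing. Attributions are centred at
#'   the estimated base value, so a resample would re-estimate that
#'   base; re-centring restores this variance component (the dominant
#'   one for crossing uncertainty), which plain pair resampling cannot
#'   see. [bootstrap_threshold_refit()] is the exact but expensive
#'   version.
#' @param refit optional function(resampled pairs) returning new pairs —
#'   a hook for custom resample post-processing.
#' @return object of class \code{"threshold_estimate"}: list with
#'   \code{point}, \code{ci_low}, \code{ci_high}, \code{direction},
#'   \code{n_boot}, \code{level}, \code{unstable_fraction},
#'   \code{unstable} (logical), \code{all_crossings},
#'   \code{boot_points}.
#' @export
bootstrap_threshold <- function(pairs, span = 0.3, n_boot = 1000L, seed = 1L,
                                level = 0.95, grid_n = 200L,
                                which_crossing = "first", recenter = FALSE,
                                refit = NULL) {
  stopifnot(all(c("x", "phi") %in% names(pairs)), n_boot >= 1L,
            level > 0, level < 1)
  full <- lowess_fit(pairs$x, pairs$phi, span = span, grid_n = grid_n)
  cr <- zero_crossings(full)
  if (nrow(cr) == 0L) stop("the full-data curve never crosses zero")
  pick <- if (identical(which_crossing, "first")) 1L
          else if (identical(which_crossing, "last")) nrow(cr)
          else as.integer(which_crossing)
  if (pick < 1L || pick > nrow(cr)) stop("which_crossing out of range")
  point <- cr$x[pick]; direction <- cr$direction[pick]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(pairs)
  boot_points <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bp <- pairs[idx, , drop = FALSE]
    if (recenter) bp$phi <- bp$phi - mean(bp$phi)
    if (!is.null(refit)) bp <- refit(bp)
    cv <- tryCatch(lowess_fit(bp$x, bp$phi, span = span, grid_n = grid_n),
                   error = function(e) NULL, warning = function(w) {
                     suppressWarnings(lowess_fit(bp$x, bp$phi, span = span,
                                                 grid_n = grid_n))
                   })
    if (is.null(cv)) next
    bc <- zero_crossings(cv)
    bc <- bc[bc$direction == direction, , drop = FALSE]
    if (nrow(bc) == 0L) next
    boot_points[b] <- bc$x[which.min(abs(bc$x - point))]
  }
  got <- boot_points[!is.na(boot_points)]
  unstable_fraction <- 1 - length(got) / n_boot
  if (length(got) == 0L) stop("no bootstrap resample produced a matching crossing")
  a <- (1 - level) / 2
  qs <- stats::quantile(got, c(a, 1 - a), names = FALSE, type = 7)
  structure(list(point = point, ci_low = qs[1], ci_high = qs[2],
                 direction = direction, n_boot = as.integer(n_boot),
                 level = level, unstable_fraction = unstable_fraction,
                 unstable = unstable_fraction > 0.5,
                 all_crossings = cr, boot_points = boot_points,
                 span = span, seed = as.integer(seed)),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("Threshold %.*g (%d%% CI %.*g-%.*g), direction %s, %d resamples",
              digits, x$point, round(100 * x$level), digits, x$ci_low,
              digits, x$ci_high, x$direction, x$n_boot))
  if (x$unstable_fraction > 0)
    cat(sprintf(", %.1f%% resamples without a matching crossing",
                100 * x$unstable_fraction))
  if (x$unstable) cat("  [UNSTABLE]")
  cat("\n")
  if (nrow(x$all_crossings) > 1L) {
    cat("all crossings:\n"); print(x$all_crossings)
  }
  invisible(x)
}

#' Full-refit bootstrap for a threshold
#'
#' The expensive bootstrap mode: resamples the panel rows with
#' replacement, refits the model and its attributions on each resample,
#' and re-estimates the zero crossing, so the interval reflects model
#' fitting and attribution re-centring variability as well as smoothing
#' noise. The cheap [bootstrap_threshold()] mode resamples only the
#' (x, attribution) pairs and holds the fitted model fixed.
#'
#' @param panel data frame with outcome and features.
#' @param formula model formula.
#' @param feature feature whose threshold is estimated.
#' @param family,params model family and overrides (see [hse_model()]).
#' @param span LOWESS span.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param level confidence level.
#' @param grid_n grid resolution.
#' @param which_crossing headline-crossing selector, as in
#'   [bootstrap_threshold()].
#' @return a \code{"threshold_estimate"} (see [bootstrap_threshold()]).
#' @export
bootstrap_threshold_refit <- function(panel, formula, feature,
                                      family = "xgboost", params = list(),
                                      span = 0.3, n_boot = 200L, seed = 1L,
                                      level = 0.95, grid_n = 200L,
                                      which_crossing = "first") {
  fit_scatter <- function(dat, fit_seed) {
    m <- hse_model(formula, dat, family = family, params = params,
                   seed = fit_seed)
    A <- compute_attributions(m, dat, seed = fit_seed)
    attribution_scatter(A, feature)
  }
  sc <- fit_scatter(panel, seed)
  full <- lowess_fit(sc$x, sc$phi, span = span, grid_n = grid_n)
  cr <- zero_crossings(full)
  if (nrow(cr) == 0L) stop("the full-data curve never crosses zero")
  pick <- if (identical(which_crossing, "first")) 1L
          else if (identical(which_crossing, "last")) nrow(cr)
          else as.integer(which_crossing)
  point <- cr$x[pick]; direction <- cr$direction[pick]
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(panel)
  idx_draws <- replicate(n_boot, sample.int(n, n, replace = TRUE),
                         simplify = FALSE)
  boot_points <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    bp <- tryCatch(
      suppressWarnings(fit_scatter(panel[idx_draws[[b]], , drop = FALSE],
                                   seed + b)),
      error = function(e) NULL)
    if (is.null(bp)) next
    cv <- tryCatch(suppressWarnings(
      lowess_fit(bp$x, bp$phi, span = span, grid_n = grid_n)),
      error = function(e) NULL)
    if (is.null(cv)) next
    bc <- zero_crossings(cv)
    bc <- bc[bc$direction == direction, , drop = FALSE]
    if (nrow(bc) == 0L) next
    boot_points[b] <- bc$x[which.min(abs(bc$x - point))]
  }
  got <- boot_points[!is.na(boot_points)]
  unstable_fraction <- 1 - length(got) / n_boot
  if (length(got) == 0L) stop("no bootstrap resample produced a matching crossing")
  a <- (1 - level) / 2
  qs <- stats::quantile(got, c(a, 1 - a), names = FALSE, type = 7)
  structure(list(point = point, ci_low = qs[1], ci_high = qs[2],
                 direction = direction, n_boot = as.integer(n_boot),
                 level = level, unstable_fraction = unstable_fraction,
                 unstable = unstable_fraction > 0.5,
                 all_crossings = cr, boot_points = boot_points,
                 span = span, seed = as.integer(seed)),
            class = "threshold_estimate")
}

#' Detect a terminal plateau in a smoothed curve
#'
#' Finds the earliest grid point after which the absolute local slope
#' (finite differences of the fitted values) stays below the tolerance
#' through the end of the grid.
#'
#' @param curve a [lowess_fit()] result.
#' @param slope_tolerance absolute slope bound, in outcome units per
#'   feature unit.
#' @return list with \code{start} (feature units) and
#'   \code{slope_tolerance}, or \code{NULL} when no plateau exists.
#' @export
detect_plateau <- function(curve, slope_tolerance) {
  gx <- curve$grid_x; fy <- curve$fitted_y
  stopifnot(length(gx) >= 2L, slope_tolerance >= 0)
  slopes <- diff(fy) / diff(gx)
  flat <- abs(slopes) <= slope_tolerance
  if (!flat[length(flat)]) return(NULL)
  run_start <- length(flat)
  while (run_start > 1L && flat[run_start - 1L]) run_start <- run_start - 1L
  list(start = gx[run_start], slope_tolerance = slope_tolerance)
}
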