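#' One-feature partial dependence
#'
#' Average model prediction as one feature is swept over a grid while
#' every other feature keeps its observed values: at grid value g the
#' partial dependence is the mean prediction over the sample rows with
#' the feature overwritten by g.
#'
#' @param model a fitted [hse_model()] (or any object with a
#'   \code{predict(object, newdata)} method over data frames).
#' @param X data frame of sample rows to average over.
#' @param feature feature name.
#' @param grid numeric evaluation values; default
#'   [quantile_grid()] of the observed feature.
#' @param grid_n grid size when \code{grid} is not given.
#' @return data frame with columns \code{x} (grid) and \code{pd} (mean
#'   prediction, outcome units).
#' @export
pdp_1d <- function(model, X, feature, grid = NULL, grid_n = 20L) {
  if (!feature %in% names(X)) stop("unknown feature: ", feature)
  if (is.null(grid)) grid <- quantile_grid(X[[feature]], grid_n)
  if (length(grid) == 0L) stop("empty grid")
  stopifnot(!is.unsorted(grid))
  pd <- vapply(grid, function(g) {
    Xg <- X
    Xg[[feature]] <- g
    mean(predict(model, Xg))
  }, numeric(1))
  data.frame(x = grid, pd = pd)
}

#' Two-feature partial dependence surface
#'
#' Mean prediction over the sample with two features jointly overwritten
#' on a grid — the standard device for reading interaction structure:
#' for an additive model the surface is exactly the outer sum of the two
#' one-feature curves minus the constant mean prediction.
#'
#' @param model,X as in [pdp_1d()].
#' @param feature_a,feature_b distinct feature names.
#' @param grid_a,grid_b evaluation grids (default quantile grids).
#' @param grid_n default grid size.
#' @return object of class \code{"pdp_grid"}: list with
#'   \code{feature_a}, \code{feature_b}, \code{grid_a}, \code{grid_b}
#'   and \code{surface} (length(grid_a) x length(grid_b) matrix of mean
#'   predictions).
#' @export
pdp_2d <- function(model, X, feature_a, feature_b,
                   grid_a = NULL, grid_b = NULL, grid_n = 20L) {
  if (identical(feature_a, feature_b)) stop("feature_a and feature_b must differ")
  for (f in c(feature_a, feature_b))
    if (!f %in% names(X)) stop("unknown feature: ", f)
  if (is.null(grid_a)) grid_a <- quantile_grid(X[[feature_a]], grid_n)
  if (is.null(grid_b)) grid_b <- quantile_grid(X[[feature_b]], grid_n)
  if (length(grid_a) == 0L || length(grid_b) == 0L) stop("empty grid")
  surface <- matrix(NA_real_, length(grid_a), length(grid_b))
  for (u in seq_along(grid_a)) {
    # one prediction batch per grid_a value, all grid_b values stacked
    Xg <- X[rep(seq_len(nrow(X)), times = length(grid_b)), , drop = FALSE]
    Xg[[feature_a]] <- grid_a[u]
    Xg[[feature_b]] <- rep(grid_b, each = nrow(X))
    p <- predict(model, Xg)
    surface[u, ] <- colMeans(matrix(p, nrow = nrow(X)))
  }
  structure(list(feature_a = feature_a, feature_b = feature_b,
                 grid_a = grid_a, grid_b = grid_b, surface = surface),
            class = "pdp_grid")
}

#' Quantile evaluation grid for a feature
#'
#' Unique empirical quantiles clipped at the 1st and 99th percentiles —
#' grids that respect the skewed marginals of provincial indicators.
#'
#' @param x observed feature values.
#' @param n number of quantiles (default 20).
#' @return increasing numeric vector (duplicates removed).
#' @export
quantile_grid <- function(x, n = 20L) {
  stopifnot(n >= 1L)
  qs <- stats::quantile(x, probs = seq(0.01, 0.99, length.out = n), names = FALSE)
  unique(qs)
}

#' @export
print.pdp_grid <- function(x, ...) {
  cat("Partial dependence surface:", x$feature_a, "x", x$feature_b,
      sprintf("(%d x %d grid), value range [%.4g, %.4g]\n",
              length(x$grid_a), length(x$grid_b),
              min(x$surface), max(x$surface)))
  invisible(x)
}

#' Long-format export of a partial dependence surface
#'
#' @param x a [pdp_2d()] result.
#' @param ... unused.
#' @return data frame with columns \code{grid_a}, \code{grid_b},
#'   \code{value}.
#' @export
as.data.frame.pdp_grid <- function(x, ...) {
  data.frame(grid_a = rep(x$grid_a, times = length(x$grid_b)),
             grid_b = rep(x$grid_b, each = length(x$grid_a)),
             value = as.vector(x$surface))
}

#' Non-additivity statistic of a surface
#'
#' Maximum absolute deviation between a two-feature surface and its
#' best additive (outer-sum) reconstruction from row and column means;
#' zero for a perfectly additive model, larger under interaction.
#'
#' @param x a [pdp_2d()] result.
#' @return nonnegative scalar in outcome units.
#' @export
pdp_nonadditivity <- function(x) {
  S <- x$surface
  recon <- outer(rowMeans(S), colMeans(S), "+") - mean(S)
  max(abs(S - recon))
}
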