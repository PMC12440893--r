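#' Derived settlement indicators from raw totals
#'
#' Computes the four settlement indicators that are ratios of raw
#' statistical-yearbook totals: road area per capita (RAPC, m2/person),
#' sanitation vehicles per 10,000 population (NSV), population density
#' (PD, persons/km2) and urbanisation rate (UR, percent of the resident
#' population that is urban).
#'
#' @param raw data frame with columns \code{road_area} (m2),
#'   \code{resident_pop_year_end} (persons), \code{sanitation_vehicles}
#'   (units), \code{admin_area} (km2), \code{urban_pop} (persons).
#' @return data frame with columns \code{RAPC}, \code{NSV}, \code{PD},
#'   \code{UR}.
#' @export
derive_indicators <- function(raw) {
  need <- c("road_area", "resident_pop_year_end", "sanitation_vehicles",
            "admin_area", "urban_pop")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing raw columns: ", paste(miss, collapse = ", "))
  bad <- which(raw$resident_pop_year_end <= 0 | raw$admin_area <= 0)
  if (length(bad))
    stop("non-positive population or area in rows: ", paste(bad, collapse = ", "))
  data.frame(
    RAPC = raw$road_area / raw$resident_pop_year_end,
    NSV  = raw$sanitation_vehicles / raw$resident_pop_year_end * 1e4,
    PD   = raw$resident_pop_year_end / raw$admin_area,
    UR   = raw$urban_pop / raw$resident_pop_year_end * 100
  )
}

#' Fill interior gaps in a yearly series by linear interpolation
#'
#' Used for indicators observed only in census/survey years (typically
#' average life expectancy): missing years strictly between two observed
#' anchors are filled on the straight line joining the nearest anchors;
#' observed values are never altered. Gaps before the first or after the
#' last anchor are refused rather than extrapolated.
#'
#' @param years integer vector of years (strictly increasing).
#' @param values numeric vector with \code{NA} at missing years.
#' @return numeric vector with interior \code{NA}s replaced.
#' @export
interpolate_series <- function(years, values) {
  stopifnot(length(years) == length(values), !is.unsorted(years, strictly = TRUE))
  obs <- which(!is.na(values))
  if (length(obs) < 2L) stop("need at least 2 observed anchor years")
  gaps <- which(is.na(values))
  if (length(gaps) == 0L) return(values)
  if (any(gaps < min(obs)) || any(gaps > max(obs)))
    stop("gap outside the anchor span: interior interpolation only, no extrapolation")
  out <- stats::approx(years[obs], values[obs], xout = years, method = "linear")$y
  out[obs] <- values[obs]
  out
}

#' Pairwise Pearson correlation screen
#'
#' Computes the full correlation matrix of a set of indicator columns
#' and flags (with a warning, not an error) every pair whose absolute
#' correlation reaches the limit — the usual pre-check before pooling
#' indicators into a composite index.
#'
#' @param X numeric matrix or data frame with at least two non-constant
#'   columns.
#' @param limit absolute-correlation bound (default 0.6).
#' @return list with \code{correlations} (symmetric matrix, unit
#'   diagonal) and \code{flagged} (data frame of offending pairs, possibly
#'   empty).
#' @export
correlation_screen <- function(X, limit = 0.6) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 columns")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  idx <- which(abs(R) >= limit & upper.tri(R), arr.ind = TRUE)
  flagged <- data.frame(a = colnames(X)[idx[, 1]], b = colnames(X)[idx[, 2]],
                        r = R[idx])
  if (nrow(flagged))
    warning(sprintf("%d indicator pair(s) with |r| >= %.2f", nrow(flagged), limit))
  list(correlations = R, flagged = flagged)
}

#' Direction-aware min-max normalisation
#'
#' Rescales each indicator column to \eqn{[0, 1]} so that larger always
#' means better: positive-direction columns map min to 0 and max to 1;
#' negative-direction columns map max to 0 and min to 1. A constant
#' (degenerate) column carries no information and is set to 0 with a
#' warning; the entropy step then assigns it zero weight.
#'
#' @param X numeric matrix (samples x indicators) with column names.
#' @param directions named character vector, one \code{"positive"} or
#'   \code{"negative"} entry per column of \code{X}.
#' @return normalised matrix of the same shape.
#' @export
normalize_decision <- function(X, directions) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names")
  miss <- setdiff(colnames(X), names(directions))
  if (length(miss)) stop("missing direction tag for: ", paste(miss, collapse = ", "))
  if (any(is.na(X))) stop("X contains missing values")
  if (nrow(X) < 2L) stop("need at least 2 samples")
  out <- X
  for (j in seq_len(ncol(X))) {
    d <- directions[[colnames(X)[j]]]
    if (!d %in% c("positive", "negative"))
      stop("direction for ", colnames(X)[j], " must be 'positive' or 'negative'")
    lo <- min(X[, j]); hi <- max(X[, j])
    if (hi == lo) {
      warning("constant indicator column '", colnames(X)[j],
              "' normalised to 0 (will receive zero weight)")
      out[, j] <- 0
    } else if (d == "positive") {
      out[, j] <- (X[, j] - lo) / (hi - lo)
    } else {
      out[, j] <- (hi - X[, j]) / (hi - lo)
    }
  }
  out
}

#' Entropy weights of normalised indicators
#'
#' Shannon-entropy weighting: each column is turned into proportions
#' \eqn{r_{ij} = x'_{ij} / \sum_i x'_{ij}}, its information entropy is
#' \eqn{e_j = -\frac{1}{\ln m}\sum_i r_{ij}\ln r_{ij}} (with
#' \eqn{0\ln 0 \equiv 0}), the divergence is \eqn{d_j = 1 - e_j}, and
#' weights are the divergences normalised to sum to one — an indicator's
#' weight grows with its cross-sample information content.
#'
#' @param Xn nonnegative normalised matrix (samples x indicators).
#' @return list with \code{weights}, \code{entropy}, \code{divergence}
#'   and \code{proportions}.
#' @export
entropy_weights <- function(Xn) {
  Xn <- as.matrix(Xn)
  if (any(Xn < 0)) stop("normalised matrix must be nonnegative")
  m <- nrow(Xn)
  if (m < 2L) stop("need at least 2 samples")
  csum <- colSums(Xn)
  R <- sweep(Xn, 2, ifelse(csum > 0, csum, 1), "/")
  plogp <- R * log(R)
  plogp[R == 0] <- 0
  e <- -colSums(plogp) / log(m)
  e[csum == 0] <- 1            # degenerate column: maximal entropy, zero weight
  d <- 1 - e
  if (all(d <= 0)) stop("all indicator columns are degenerate; weights undefined")
  w <- d / sum(d)
  list(weights = w, entropy = e, divergence = d, proportions = R)
}

#' TOPSIS closeness over a weighted normalised matrix
#'
#' Weights each normalised column, locates the column-wise ideal and
#' anti-ideal points, and scores every sample by its relative Euclidean
#' closeness to the ideal:
#' \eqn{C_i = D_i^- / (D_i^+ + D_i^-) \in [0, 1]}, 1 at the ideal point
#' and 0 at the anti-ideal.
#'
#' @param Xn normalised matrix (samples x indicators).
#' @param weights nonnegative weights summing to 1, one per column.
#' @return list with \code{closeness}, \code{weighted}, \code{ideal},
#'   \code{anti_ideal}, \code{dist_pos}, \code{dist_neg}.
#' @export
topsis_closeness <- function(Xn, weights) {
  Xn <- as.matrix(Xn)
  stopifnot(length(weights) == ncol(Xn), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  V <- sweep(Xn, 2, weights, "*")
  s_pos <- apply(V, 2, max)
  s_neg <- apply(V, 2, min)
  d_pos <- sqrt(rowSums(sweep(V, 2, s_pos)^2))
  d_neg <- sqrt(rowSums(sweep(V, 2, s_neg)^2))
  denom <- d_pos + d_neg
  if (any(denom == 0))
    stop("sample(s) with zero distance to both ideal points; matrix is degenerate")
  list(closeness = d_neg / denom, weighted = V, ideal = s_pos,
       anti_ideal = s_neg, dist_pos = d_pos, dist_neg = d_neg)
}

#' Build the Health Level Index for a panel
#'
#' Composes direction-aware normalisation, entropy weighting and TOPSIS
#' closeness over the pooled sample of province-year rows, appending the
#' resulting composite index (one value per row, in \eqn{[0,1]}, larger =
#' healthier) to the panel. Pooling all rows yields a single weight
#' vector and index values comparable across provinces and years.
#'
#' @param panel data frame holding the indicator columns.
#' @param directions named character vector of \code{"positive"} /
#'   \code{"negative"} tags, one per indicator; its names select the
#'   indicator columns.
#' @param column name of the appended index column (default \code{"HLI"}).
#' @return an object of class \code{"hli"}: list with \code{panel} (input
#'   plus index column), \code{closeness}, \code{weights},
#'   \code{entropy}, \code{normalized}, \code{ideal}, \code{anti_ideal},
#'   \code{directions}.
#' @export
build_hli <- function(panel, directions = health_indicator_directions(),
                      column = "HLI") {
  miss <- setdiff(names(directions), names(panel))
  if (length(miss)) stop("panel lacks indicator column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(panel[, names(directions), drop = FALSE])
  if (any(is.na(X))) stop("indicator columns contain missing values")
  Xn <- normalize_decision(X, directions)
  ew <- entropy_weights(Xn)
  tp <- topsis_closeness(Xn, ew$weights)
  out <- panel
  out[[column]] <- tp$closeness
  structure(list(panel = out, closeness = tp$closeness, weights = ew$weights,
                 entropy = ew$entropy, normalized = Xn, ideal = tp$ideal,
                 anti_ideal = tp$anti_ideal, dist_pos = tp$dist_pos,
                 dist_neg = tp$dist_neg, directions = directions,
                 column = column),
            class = "hli")
}

#' @export
print.hli <- function(x, digits = 4, ...) {
  cat("Entropy-TOPSIS composite index over", length(x$closeness), "pooled samples\n")
  cat("Entropy weights:\n")
  print(round(x$weights, digits))
  cat("Index (", x$column, ") range: [",
      format(min(x$closeness), digits = digits), ", ",
      format(max(x$closeness), digits = digits), "]\n", sep = "")
  invisible(x)
}

#' @export
summary.hli <- function(object, ...) {
  structure(list(weights = object$weights, entropy = object$entropy,
                 closeness_summary = summary(object$closeness),
                 n = length(object$closeness)), class = "summary.hli")
}

#' @export
print.summary.hli <- function(x, ...) {
  cat("Entropy-TOPSIS index, n =", x$n, "\n")
  cat("weights: "); print(round(x$weights, 4))
  cat("entropy: "); print(round(x$entropy, 4))
  print(x$closeness_summary)
  invisible(x)
}
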