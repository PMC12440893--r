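#' Specify a planted feature effect
#'
#' Describes how one settlement feature contributes to the latent health
#' outcome in a synthetic panel. Three shapes are supported: a straight
#' line, a continuous piecewise-linear kink (slope changes at a
#' breakpoint, the value crossing zero there), and a plateau (linear up
#' to \code{plateau_start}, flat afterwards). All shapes are continuous
#' in the feature value.
#'
#' @param feature name of the feature column the effect applies to.
#' @param shape one of \code{"linear"}, \code{"piecewise"}, \code{"plateau"}.
#' @param slope slope for the linear shape (outcome units per feature unit).
#' @param breakpoint kink location for the piecewise shape (feature units).
#' @param slope_below,slope_above slopes on either side of the breakpoint
#'   (piecewise) or below \code{plateau_start} (plateau; the slope above a
#'   plateau is identically zero).
#' @param plateau_start feature value where the plateau begins.
#' @param offset constant added to the contribution (outcome units).
#'
#' @return an object of class \code{"effect_spec"}.
#' @seealso [evaluate_effect()], [synthetic_spec()]
#' @export
effect_spec <- function(feature, shape = c("linear", "piecewise", "plateau"),
                        slope = NULL, breakpoint = NULL,
                        slope_below = NULL, slope_above = NULL,
                        plateau_start = NULL, offset = 0) {
  shape <- match.arg(shape)
  stopifnot(is.character(feature), length(feature) == 1L, nzchar(feature),
            is.numeric(offset), length(offset) == 1L, is.finite(offset))
  e <- list(feature = feature, shape = shape, offset = offset)
  if (shape == "linear") {
    if (is.null(slope)) stop("linear effect requires `slope`")
    e$slope <- as.numeric(slope)
  } else if (shape == "piecewise") {
    if (is.null(breakpoint) || is.null(slope_below) || is.null(slope_above))
      stop("piecewise effect requires `breakpoint`, `slope_below`, `slope_above`")
    e$breakpoint <- as.numeric(breakpoint)
    e$slope_below <- as.numeric(slope_below)
    e$slope_above <- as.numeric(slope_above)
  } else {
    if (is.null(plateau_start) || is.null(slope_below))
      stop("plateau effect requires `plateau_start` and `slope_below`")
    e$plateau_start <- as.numeric(plateau_start)
    e$slope_below <- as.numeric(slope_below)
  }
  structure(e, class = "effect_spec")
}

#' Evaluate a planted effect at feature values
#'
#' @param e an [effect_spec()].
#' @param x numeric vector of feature values.
#' @return numeric vector of outcome contributions, continuous in \code{x};
#'   a piecewise effect takes the same value at its breakpoint from both
#'   branches, and a plateau is constant beyond \code{plateau_start}.
#' @export
evaluate_effect <- function(e, x) {
  if (!inherits(e, "effect_spec")) stop("`e` must be an effect_spec")
  stopifnot(is.numeric(x), all(is.finite(x)))
  y <- switch(e$shape,
    linear = e$slope * x,
    piecewise = ifelse(x < e$breakpoint,
                       e$slope_below * (x - e$breakpoint),
                       e$slope_above * (x - e$breakpoint)),
    plateau = ifelse(x < e$plateau_start,
                     e$slope_below * (x - e$plateau_start),
                     0),
    stop("unknown effect shape: ", e$shape))
  y + e$offset
}

#' Specify a synthetic province-year panel
#'
#' Defines the generating conditions for a balanced panel: grid of units
#' and periods, per-feature uniform ranges, a list of planted effects
#' forming the latent outcome, and homoscedastic Gaussian outcome noise.
#' Feature marginals are independent uniforms by default; an optional
#' Gaussian-copula correlation stresses downstream stages with dependent
#' features.
#'
#' @param feature_ranges named list of \code{c(min, max)} numeric pairs,
#'   one per feature, in feature units.
#' @param effects non-empty list of [effect_spec()] objects; every effect
#'   must name a feature in \code{feature_ranges}, and a piecewise
#'   breakpoint / plateau start must lie inside that feature's range.
#' @param n_units,n_periods panel dimensions (defaults: 31 units over
#'   11 periods, i.e. 341 rows).
#' @param noise_sd standard deviation of additive Gaussian outcome noise,
#'   in outcome units; must be \eqn{\ge 0}.
#' @param intercept baseline outcome level added to every row.
#' @param seed integer seed; the generated panel is a pure function of
#'   the spec, including this seed.
#' @param first_year calendar year of the first period (cosmetic).
#' @param copula_corr optional feature correlation: a single value in
#'   (-1, 1) giving a common pairwise correlation, or a full positive
#'   definite correlation matrix.
#'
#' @return an object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(feature_ranges, effects,
                           n_units = 31L, n_periods = 11L,
                           noise_sd = 0.03, intercept = 0,
                           seed = 1L, first_year = 2012L,
                           copula_corr = NULL) {
  stopifnot(is.list(feature_ranges), length(feature_ranges) >= 1L,
            !is.null(names(feature_ranges)), all(nzchar(names(feature_ranges))))
  for (nm in names(feature_ranges)) {
    r <- feature_ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop("feature_ranges[['", nm, "']] must be a finite (min, max) pair with min < max")
  }
  if (!is.list(effects) || length(effects) == 0L)
    stop("`effects` must be a non-empty list of effect_spec objects")
  for (e in effects) {
    if (!inherits(e, "effect_spec")) stop("every effect must be an effect_spec")
    if (!e$feature %in% names(feature_ranges))
      stop("effect names unknown feature: ", e$feature)
    r <- feature_ranges[[e$feature]]
    knot <- switch(e$shape, piecewise = e$breakpoint, plateau = e$plateau_start, NULL)
    if (!is.null(knot) && (knot <= r[1] || knot >= r[2]))
      stop("breakpoint/plateau_start for ", e$feature,
           " must lie strictly inside its generating range")
  }
  stopifnot(n_units >= 1L, n_periods >= 1L,
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  if (!is.null(copula_corr) && length(copula_corr) == 1L)
    stopifnot(abs(copula_corr) < 1)
  structure(list(feature_ranges = feature_ranges, effects = effects,
                 n_units = as.integer(n_units), n_periods = as.integer(n_periods),
                 noise_sd = as.numeric(noise_sd), intercept = as.numeric(intercept),
                 seed = as.integer(seed), first_year = as.integer(first_year),
                 copula_corr = copula_corr),
            class = "synthetic_spec")
}

# Draw the feature block for a spec: independent uniforms, or a Gaussian
# copula with uniform marginals when copula_corr is set.
draw_features <- function(spec, n) {
  p <- length(spec$feature_ranges)
  nms <- names(spec$feature_ranges)
  if (is.null(spec$copula_corr)) {
    U <- matrix(stats::runif(n * p), nrow = n, ncol = p)
  } else {
    R <- spec$copula_corr
    if (length(R) == 1L) {
      R <- matrix(R, p, p)
      diag(R) <- 1
    }
    L <- chol(R)
    Z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p) %*% L
    U <- stats::pnorm(Z)
  }
  X <- vapply(seq_len(p), function(j) {
    r <- spec$feature_ranges[[j]]
    r[1] + U[, j] * (r[2] - r[1])
  }, numeric(n))
  colnames(X) <- nms
  X
}

#' Generate a synthetic province-year panel with known truth
#'
#' Draws features within their declared ranges, forms the latent outcome
#' as the sum of planted effect contributions (plus the intercept), and
#' adds Gaussian noise to produce the observed outcome column
#' \code{HLI}. Regenerating with the same spec reproduces the panel
#' exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class \code{"generated_panel"}: a list with
#'   \code{panel} (data frame \code{province, year, <features>, HLI}),
#'   \code{true_index} (latent outcome before noise) and \code{spec}.
#' @export
generate_panel <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("`spec` must be a synthetic_spec")
  n <- spec$n_units * spec$n_periods
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  X <- draw_features(spec, n)
  latent <- rep(spec$intercept, n)
  for (e in spec$effects) latent <- latent + evaluate_effect(e, X[, e$feature])
  noise <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else numeric(n)
  panel <- data.frame(
    province = rep(sprintf("P%02d", seq_len(spec$n_units)), each = spec$n_periods),
    year = rep(spec$first_year + seq_len(spec$n_periods) - 1L, times = spec$n_units),
    X,
    HLI = latent + noise,
    check.names = FALSE
  )
  structure(list(panel = panel, true_index = latent, spec = spec),
            class = "generated_panel")
}

# Save/restore the global RNG state so generators are pure functions of
# their spec without disturbing the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.generated_panel <- function(x, ...) {
  cat("Synthetic province-year panel:",
      nrow(x$panel), "rows (", x$spec$n_units, "units x",
      x$spec$n_periods, "periods ),",
      length(x$spec$feature_ranges), "features,",
      length(x$spec$effects), "planted effects\n")
  cat("  outcome noise sd:", x$spec$noise_sd,
      " seed:", x$spec$seed, "\n")
  invisible(x)
}

#' Generate the four health indicator columns
#'
#' Emits the standard quartet of provincial health indicators — incidence
#' and mortality of class A/B notifiable infectious diseases, human
#' mortality (all negative-direction) and average life expectancy
#' (positive-direction) — as monotone affine transforms of a single
#' latent health score plus small Gaussian noise, so the latent ranking
#' is recoverable by a composite index.
#'
#' @param x a [synthetic_spec()] or a [generate_panel()] result; the
#'   latent score is the panel's \code{true_index}.
#' @param indicator_noise fraction of each indicator's span used as the
#'   noise standard deviation (0 gives perfectly rank-aligned columns).
#' @return the panel data frame with four indicator columns appended:
#'   \code{incidence_ab}, \code{mortality_ab}, \code{human_mortality},
#'   \code{life_expectancy}. Attribute \code{"latent"} carries the
#'   latent score used.
#' @export
generate_health_indicators <- function(x, indicator_noise = 0.01) {
  gp <- if (inherits(x, "synthetic_spec")) generate_panel(x) else x
  if (!inherits(gp, "generated_panel")) stop("`x` must be a synthetic_spec or generated_panel")
  stopifnot(indicator_noise >= 0)
  latent <- gp$true_index
  n <- length(latent)
  rng <- range(latent)
  z <- if (diff(rng) > 0) (latent - rng[1]) / diff(rng) else rep(0.5, n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(gp$spec$seed + 104729L)  # offset stream so features are untouched
  spans <- c(incidence_ab = 120, mortality_ab = 1.0,
             human_mortality = 3, life_expectancy = 8)
  noise <- function(span) if (indicator_noise > 0)
    stats::rnorm(n, 0, indicator_noise * span) else numeric(n)
  out <- gp$panel
  out$incidence_ab    <- 250 - spans[1] * z + noise(spans[1])   # per 100,000, negative direction
  out$mortality_ab    <- 1.6 - spans[2] * z + noise(spans[2])   # per 100,000, negative direction
  out$human_mortality <- 8.0 - spans[3] * z + noise(spans[3])   # percent, negative direction
  out$life_expectancy <- 72  + spans[4] * z + noise(spans[4])   # years, positive direction
  attr(out, "latent") <- latent
  out
}

#' Direction tags of the four generated health indicators
#'
#' @return named character vector mapping indicator column names to
#'   \code{"positive"} or \code{"negative"}.
#' @export
health_indicator_directions <- function() {
  c(incidence_ab = "negative", mortality_ab = "negative",
    human_mortality = "negative", life_expectancy = "positive")
}

# Scale a unit piecewise/plateau effect so its contribution has the
# requested sd under the uniform feature marginal (computed on a fine grid).
scale_effect_to_sd <- function(e, lo, hi, target_sd) {
  g <- seq(lo, hi, length.out = 2001L)
  y <- evaluate_effect(e, g)
  s <- stats::sd(y)
  if (s == 0) stop("cannot scale a flat effect")
  k <- target_sd / s
  for (f in intersect(c("slope", "slope_below", "slope_above", "offset"), names(e)))
    e[[f]] <- e[[f]] * k
  e
}

#' Mean-zero sign-changing piecewise effect
#'
#' Continuous piecewise-linear effect crossing zero at its breakpoint,
#' with the slope ratio chosen so the contribution integrates to zero
#' over the uniform generating range \code{[lo, hi]}. Centred
#' attributions of such an effect change sign exactly at the kink,
#' which makes the breakpoint the estimand of the zero-crossing
#' threshold analysis.
#'
#' @param feature feature name.
#' @param b breakpoint, strictly inside \code{(lo, hi)}.
#' @param lo,hi generating range of the feature.
#' @param target_sd standard deviation of the contribution under the
#'   uniform marginal (outcome units).
#' @param sign \code{+1} for an increasing effect (crossing \code{-+}),
#'   \code{-1} for a decreasing one (\code{+-}).
#' @return an [effect_spec()].
#' @export
piecewise_effect_meanzero <- function(feature, b, lo, hi, target_sd, sign = 1) {
  stopifnot(lo < b, b < hi, target_sd > 0, sign %in% c(-1, 1))
  ratio <- ((b - lo) / (hi - b))^2   # slope_above / slope_below for zero mean
  e <- effect_spec(feature, "piecewise", breakpoint = b,
                   slope_below = sign * 1, slope_above = sign * ratio)
  scale_effect_to_sd(e, lo, hi, target_sd)
}

#' Default synthetic study conditions
#'
#' A 31-unit by 11-period panel carrying the 19 settlement-environment
#' indicators at their observed provincial ranges, with planted effects
#' on the six key features: sign-changing piecewise effects on hospital
#' bed density (NMIB, decreasing through 60.21), urbanisation rate (UR,
#' increasing through 65.73), mobile phone penetration (MPPR, through
#' 123.21), road area per capita (RAPC, through 3.99) and urban gas
#' penetration (UGPR, through 95.18), and a rising-then-flat plateau
#' effect on population density (PD, crossing zero at 517 and levelling
#' off at 1250 persons/km2). The remaining 13 indicators are pure noise
#' features. Piecewise effects are constructed mean-zero over their
#' generating range so each centred contribution changes sign exactly at
#' its breakpoint.
#'
#' @param seed integer seed.
#' @param noise_sd outcome noise standard deviation (default 0.03 against
#'   a latent-outcome sd of roughly 0.09, i.e. signal-to-noise about 3).
#' @return a [synthetic_spec()].
#' @export
synthetic_spec_default <- function(seed = 1L, noise_sd = 0.03) {
  ranges <- list(
    PCPGA = c(5.85, 22.84),  CODE = c(1.76, 192.12), SO2E = c(0.11, 174.88),
    NSV   = c(0.12, 15.02),  UWPR = c(67.57, 100),   UGPR = c(29.79, 100),
    PD    = c(2.57, 3925.87), UR  = c(22.86, 89.58), NPT  = c(0.77, 9.35),
    RAPC  = c(1.14, 13.71),  NPTV = c(5.63, 26.55),  MPPR = c(57.30, 189.46),
    NHES  = c(1133, 5534),   PLFA = c(45.66, 335.80), NMIB = c(27.15, 84.31),
    PSPSO = c(0.15, 2.77),   DUSTC = c(5, 2971.30),  LFEPE = c(17.21, 747.44),
    PCDDWC = c(91.12, 403.62))
  mz <- function(f, b, sd, sign) piecewise_effect_meanzero(
    f, b, ranges[[f]][1], ranges[[f]][2], sd, sign)
  pd_lo <- ranges$PD[1]; pd_hi <- ranges$PD[2]
  pd <- effect_spec("PD", "plateau", plateau_start = 1250,
                    slope_below = 1 / (1250 - 517),
                    offset = 0)                       # crossing at 517 after offset
  pd$offset <- -evaluate_effect(pd, 517)
  pd <- scale_effect_to_sd(pd, pd_lo, pd_hi, 0.025)
  effects <- list(
    mz("NMIB", 60.21, 0.050, sign = -1),
    mz("UR",   65.73, 0.035, sign = +1),
    mz("MPPR", 123.21, 0.035, sign = +1),
    mz("RAPC", 3.99, 0.025, sign = +1),
    mz("UGPR", 95.18, 0.020, sign = +1),
    pd)
  synthetic_spec(ranges, effects, noise_sd = noise_sd,
                 intercept = 0.6, seed = seed)
}

#' Write / read a panel as CSV
#'
#' Plain-text round trip for generated or observed panels with the
#' header layout \code{province,year,<feature...>,<indicator...>}.
#'
#' @param panel a data frame.
#' @param path file path.
#' @return \code{read_panel_csv} returns the data frame.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
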