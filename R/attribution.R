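#' Additive Shapley attributions for a fitted model
#'
#' Decomposes every prediction into a base value plus one additive
#' contribution per feature (local accuracy: base + sum of
#' contributions = prediction, checked row-wise and enforced). For the
#' boosted-tree families the exact TreeSHAP values from the xgboost
#' engine are used; for any other family the attributions are estimated
#' by permutation-path sampling (Strumbelj-Kononenko), which is exactly
#' additive by its telescoping construction at any number of
#' permutations.
#'
#' @param model a fitted [hse_model()].
#' @param X data frame of rows to explain (defaults in the pipeline to
#'   the full sample).
#' @param engine \code{"auto"} (TreeSHAP when the engine supports it,
#'   else permutation), \code{"treeshap"} or \code{"permutation"}.
#' @param nsim number of sampled permutations (permutation engine).
#' @param background background rows used to represent feature absence
#'   (permutation engine); defaults to up to \code{bg_size} seeded draws
#'   from \code{X}.
#' @param bg_size background sample cap.
#' @param seed integer seed for the permutation engine.
#' @param tol additivity tolerance relative to prediction scale; a
#'   violation is an error, never silently returned.
#' @return object of class \code{"shap_attribution"}: list with
#'   \code{phi} (n x d matrix, outcome units), \code{phi0} (base value),
#'   \code{X} (feature values aligned with \code{phi}),
#'   \code{prediction}, \code{engine}.
#' @export
compute_attributions <- function(model, X,
                                 engine = c("auto", "treeshap", "permutation"),
                                 nsim = 30L, background = NULL, bg_size = 50L,
                                 seed = 1L, tol = 1e-6) {
  if (!inherits(model, "hse_model")) stop("`model` must be an hse_model")
  engine <- match.arg(engine)
  miss <- setdiff(model$features, names(X))
  if (length(miss)) stop("X lacks feature(s): ", paste(miss, collapse = ", "))
  X <- as.data.frame(X)[, model$features, drop = FALSE]
  pred <- predict(model, X)
  if (engine == "auto")
    engine <- if (model$engine$kind == "xgb") "treeshap" else "permutation"
  if (engine == "treeshap") {
    if (model$engine$kind != "xgb")
      stop("TreeSHAP engine is only available for the boosted-tree families")
    pc <- predict(model$engine$fit, data.matrix(X), predcontrib = TRUE)
    phi0 <- mean(pc[, ncol(pc)]) + model$engine$center
    phi <- pc[, -ncol(pc), drop = FALSE]
  } else {
    ps <- permutation_shap(function(M) predict_family(model$engine, M),
                           X, nsim = nsim, background = background,
                           bg_size = bg_size, seed = seed)
    phi <- ps$phi; phi0 <- ps$phi0
  }
  colnames(phi) <- model$features
  gap <- max(abs(phi0 + rowSums(phi) - pred))
  scale <- max(1, max(abs(pred)))
  if (gap > tol * scale)
    stop(sprintf("additivity identity violated: max gap %.3g exceeds %.3g",
                 gap, tol * scale))
  structure(list(phi = phi, phi0 = phi0, X = X, prediction = pred,
                 engine = engine, additivity_gap = gap),
            class = "shap_attribution")
}

# Permutation-path Shapley sampling. For each sampled permutation the
# per-feature marginal contributions telescope from f(background row) to
# f(x), so the averaged attributions satisfy base + sum = prediction
# exactly (up to float error) regardless of nsim. Antithetic pairs
# (each permutation and its reverse) reduce variance.
permutation_shap <- function(predict_fun, X, nsim = 30L, background = NULL,
                             bg_size = 50L, seed = 1L) {
  X <- as.data.frame(X)
  n <- nrow(X); d <- ncol(X)
  stopifnot(n >= 1L, d >= 1L, nsim >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(background)) {
    background <- if (n > bg_size) X[sample.int(n, bg_size), , drop = FALSE] else X
  } else background <- as.data.frame(background)[, names(X), drop = FALSE]
  Xm <- data.matrix(X)
  Bm <- data.matrix(background)
  phi <- matrix(0, n, d)
  phi0 <- 0
  perms <- vector("list", nsim)
  for (s in seq_len(nsim))
    perms[[s]] <- if (s %% 2L == 0L) rev(perms[[s - 1L]]) else sample.int(d)
  # cycle background rows in a shuffled order rather than resampling:
  # stratification keeps the base value close to the background mean
  zrows <- rep_len(sample.int(nrow(Bm)), nsim)
  for (s in seq_len(nsim)) {
    pi_s <- perms[[s]]
    z <- Bm[zrows[s], ]
    # block of (d+1) prefix variants per explained row
    big <- Xm[rep(seq_len(n), each = d + 1L), , drop = FALSE]
    keep <- matrix(FALSE, d + 1L, d)            # prefix k keeps features pi[1..k]
    for (k in seq_len(d)) keep[(k + 1L):(d + 1L), pi_s[k]] <- TRUE
    keep_big <- keep[rep(seq_len(d + 1L), times = n), , drop = FALSE]
    big[!keep_big] <- rep(z, each = (d + 1L) * n)[!keep_big]
    f <- predict_fun(as.data.frame(big))
    fm <- matrix(f, nrow = d + 1L)              # (prefix) x (row)
    contrib <- fm[-1L, , drop = FALSE] - fm[-(d + 1L), , drop = FALSE]
    phi[, pi_s] <- phi[, pi_s] + t(contrib)
    phi0 <- phi0 + mean(fm[1L, ])               # f with no features kept
  }
  list(phi = phi / nsim, phi0 = phi0 / nsim)
}

#' Exact Shapley values by subset enumeration
#'
#' Brute-force reference: evaluates the coalition value of every feature
#' subset (features outside the coalition replaced by background rows,
#' value = mean prediction) and combines marginal contributions with the
#' exact Shapley weights. Exponential in the number of features; meant
#' for validating sampled attributions on toy models.
#'
#' @param predict_fun function taking a data frame and returning
#'   predictions.
#' @param X data frame of rows to explain (d <= 12).
#' @param background data frame of background rows.
#' @return list with \code{phi} (n x d) and \code{phi0} (scalar mean
#'   prediction over the background).
#' @export
shap_exact <- function(predict_fun, X, background) {
  X <- as.data.frame(X); background <- as.data.frame(background)[, names(X), drop = FALSE]
  n <- nrow(X); d <- ncol(X)
  if (d > 12L) stop("exact enumeration limited to 12 features")
  nb <- nrow(background)
  # coalition values v[i, S] for every bitmask S
  v <- matrix(0, n, 2^d)
  for (S in 0:(2^d - 1L)) {
    inS <- as.logical(bitwAnd(S, 2^(seq_len(d) - 1L)))
    tot <- numeric(n)
    for (b in seq_len(nb)) {
      M <- X
      for (j in which(!inS)) M[[j]] <- background[b, j]
      tot <- tot + predict_fun(M)
    }
    v[, S + 1L] <- tot / nb
  }
  phi <- matrix(0, n, d, dimnames = list(NULL, names(X)))
  fact <- factorial(0:d)
  for (j in seq_len(d)) {
    bit <- 2^(j - 1L)
    for (S in 0:(2^d - 1L)) {
      if (bitwAnd(S, bit) != 0L) next
      s <- sum(as.logical(bitwAnd(S, 2^(seq_len(d) - 1L))))
      w <- fact[s + 1L] * fact[d - s] / fact[d + 1L]
      phi[, j] <- phi[, j] + w * (v[, S + bit + 1L] - v[, S + 1L])
    }
  }
  list(phi = phi, phi0 = v[1L, 1L])
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat("Shapley attributions (", x$engine, "): ", nrow(x$phi), " rows x ",
      ncol(x$phi), " features, base value ", format(x$phi0, digits = 5),
      ", max additivity gap ", format(x$additivity_gap, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Feature importance ranking and percentage shares
#'
#' Aggregates an attribution matrix to the mean absolute contribution
#' per feature, its share of the total (percent, summing to 100), and
#' the descending importance rank (ties broken alphabetically).
#'
#' @param A a [compute_attributions()] result.
#' @return data frame with columns \code{feature}, \code{mean_abs_phi},
#'   \code{share} (percent) and \code{rank}, sorted by rank.
#' @export
importance_shares <- function(A) {
  if (!inherits(A, "shap_attribution")) stop("`A` must be a shap_attribution")
  m <- colMeans(abs(A$phi))
  if (sum(m) == 0) stop("all attributions are zero; shares undefined")
  share <- 100 * m / sum(m)
  ord <- order(-m, names(m))
  out <- data.frame(feature = names(m)[ord], mean_abs_phi = unname(m[ord]),
                    share = unname(share[ord]), rank = seq_along(m))
  rownames(out) <- NULL
  out
}

#' Attribution scatter for one feature
#'
#' Aligned (feature value, attribution) pairs sorted by the feature
#' value — the raw material for LOWESS threshold smoothing. Duplicate
#' feature values are all retained, in input order.
#'
#' @param A a [compute_attributions()] result.
#' @param feature feature name.
#' @return data frame with columns \code{x} (feature units, nondecreasing)
#'   and \code{phi} (outcome units).
#' @export
attribution_scatter <- function(A, feature) {
  if (!inherits(A, "shap_attribution")) stop("`A` must be a shap_attribution")
  if (!feature %in% colnames(A$phi)) stop("unknown feature: ", feature)
  x <- A$X[[feature]]
  ord <- order(x)   # stable: ties keep input order
  data.frame(x = x[ord], phi = A$phi[ord, feature])
}
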