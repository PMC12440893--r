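#' Model families available for benchmarking
#'
#' Six regression families spanning the usual tabular-regression
#' spectrum: \code{"xgboost"} (exact-greedy gradient-boosted trees, the
#' primary model), \code{"gbdt"} (classic unregularised gradient
#' boosting, run through the same boosting engine with the
#' regularisation terms switched off), \code{"hist_gbdt"}
#' (histogram-based gradient boosting, the LightGBM-style variant),
#' \code{"adaboost"} (AdaBoost.R2 over shallow regression trees),
#' \code{"random_forest"} and \code{"lasso"} (L1-penalised linear
#' baseline).
#'
#' @return character vector of family names.
#' @export
model_families <- function() {
  c("xgboost", "gbdt", "hist_gbdt", "adaboost", "random_forest", "lasso")
}

# Reproduction preset: the boosted families are pinned at learning rate
# 0.05, 200 estimators, depth 3; forest and lasso use their standard
# defaults (lasso's penalty picked by seeded cross-validation).
default_params <- function(family) {
  switch(family,
    xgboost = list(eta = 0.05, nrounds = 200, max_depth = 3,
                   tree_method = "exact", reg_lambda = 1, gamma = 0,
                   subsample = 1, colsample_bytree = 1),
    gbdt = list(eta = 0.05, nrounds = 200, max_depth = 3,
                tree_method = "exact", reg_lambda = 0, gamma = 0,
                subsample = 1, colsample_bytree = 1),
    hist_gbdt = list(eta = 0.05, nrounds = 200, max_depth = 3,
                     tree_method = "hist", max_bin = 256, reg_lambda = 1,
                     gamma = 0, subsample = 1, colsample_bytree = 1),
    adaboost = list(n_estimators = 100, max_depth = 3, learning_rate = 1),
    random_forest = list(ntree = 500, mtry = NULL, nodesize = 5),
    lasso = list(alpha = 1, nlambda = 100),
    stop("unknown model family: ", family))
}

fit_family <- function(family, X, y, params, seed) {
  p <- utils::modifyList(default_params(family), params)
  set.seed(seed)
  if (family %in% c("xgboost", "gbdt", "hist_gbdt")) {
    # centre the outcome so the engine works near zero: float32 tree-sum
    # round-off then stays orders of magnitude below the additive-
    # attribution identity tolerance; the centre is restored in double
    center <- mean(y)
    dtrain <- xgboost::xgb.DMatrix(data.matrix(X), label = y - center)
    booster <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = p$eta,
                    max_depth = p$max_depth, tree_method = p$tree_method,
                    lambda = p$reg_lambda, gamma = p$gamma,
                    subsample = p$subsample,
                    colsample_bytree = p$colsample_bytree,
                    max_bin = if (p$tree_method == "hist") p$max_bin else 256,
                    base_score = 0, nthread = 1, seed = seed),
      data = dtrain, nrounds = p$nrounds, verbose = 0)
    list(fit = booster, kind = "xgb", center = center)
  } else if (family == "adaboost") {
    list(fit = adaboost_r2_fit(X, y, n_estimators = p$n_estimators,
                               max_depth = p$max_depth,
                               learning_rate = p$learning_rate),
         kind = "ada")
  } else if (family == "random_forest") {
    mtry <- if (is.null(p$mtry)) max(1L, floor(ncol(X) / 3)) else p$mtry
    list(fit = randomForest::randomForest(
           x = as.data.frame(X), y = y, ntree = p$ntree, mtry = mtry,
           nodesize = p$nodesize),
         kind = "rf")
  } else if (family == "lasso") {
    Xm <- data.matrix(X)
    cv <- glmnet::cv.glmnet(Xm, y, alpha = p$alpha, nfolds = 5,
                            nlambda = p$nlambda)
    list(fit = cv, kind = "lasso")
  } else stop("unknown model family: ", family)
}

predict_family <- function(model, X) {
  switch(model$kind,
    xgb = predict(model$fit, data.matrix(X)) + model$center,
    ada = adaboost_r2_predict(model$fit, X),
    rf = unname(predict(model$fit, as.data.frame(X))),
    lasso = as.numeric(predict(model$fit, data.matrix(X), s = "lambda.min")),
    stop("unknown model kind"))
}

#' Fit a settlement-health regression model
#'
#' Uniform fit/predict contract over the six benchmark families: a
#' formula-and-data interface returning a classed object usable by the
#' attribution, threshold and partial-dependence stages. Learner
#' internals are delegated to the established engines (xgboost,
#' randomForest, glmnet, rpart); this wrapper pins their configuration
#' and seeding.
#'
#' @param formula model formula, e.g. \code{HLI ~ .} or an explicit
#'   feature list; the left-hand side names the outcome column.
#' @param data data frame holding outcome and features.
#' @param family one of [model_families()] (default \code{"xgboost"}).
#' @param params named list of hyperparameter overrides; unspecified
#'   entries fall back to the reproduction preset (learning rate 0.05,
#'   200 estimators, depth 3 for the boosted families).
#' @param seed integer seed for all fitting randomness.
#' @return object of class \code{"hse_model"} with elements
#'   \code{family}, \code{params}, \code{features}, \code{outcome},
#'   \code{seed} and the wrapped engine fit.
#' @export
hse_model <- function(formula, data, family = "xgboost", params = list(),
                      seed = 2025L) {
  family <- match.arg(family, model_families())
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- mf[, -1L, drop = FALSE]
  if (ncol(X) == 0L) stop("no predictor columns in formula")
  if (!all(vapply(X, is.numeric, logical(1))))
    stop("all predictors must be numeric")
  stopifnot(is.numeric(y))
  engine <- fit_family(family, X, y, params, seed)
  structure(list(family = family, params = params, engine = engine,
                 features = names(X), outcome = deparse(formula[[2L]]),
                 seed = as.integer(seed), n_train = nrow(X)),
            class = "hse_model")
}

#' @param object,x a fitted \code{hse_model}.
#' @param newdata data frame containing the feature columns.
#' @param ... unused.
#' @rdname hse_model
#' @export
predict.hse_model <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) stop("newdata lacks feature(s): ", paste(miss, collapse = ", "))
  predict_family(object$engine, newdata[, object$features, drop = FALSE])
}

#' @rdname hse_model
#' @export
print.hse_model <- function(x, ...) {
  cat("hse_model:", x$family, "fit of", x$outcome, "on",
      length(x$features), "features (n =", x$n_train, ", seed =", x$seed, ")\n")
  invisible(x)
}

#' Seeded train/test split of a panel
#'
#' Partitions the province-year rows into train and test sets at the
#' requested fraction: the test set takes \code{ceiling((1 -
#' train_fraction) * n)} rows (largest remainder), so 341 rows at 0.8
#' give 272 train / 69 test. Resampling is at the row (province-year)
#' level and fully reproducible under the seed.
#'
#' @param panel data frame.
#' @param train_fraction proportion of rows for training, in (0, 1).
#' @param seed integer seed (default 2025).
#' @return list with \code{train}, \code{test} (data frames) and
#'   \code{train_idx}, \code{test_idx} (sorted row indices).
#' @export
split_panel <- function(panel, train_fraction = 0.8, seed = 2025L) {
  n <- nrow(panel)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie in (0, 1)")
  n_test <- as.integer(ceiling((1 - train_fraction) * n))
  if (n_test == 0L || n_test == n) stop("degenerate split for n = ", n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  test_idx <- sort(perm[seq_len(n_test)])
  train_idx <- sort(perm[-seq_len(n_test)])
  list(train = panel[train_idx, , drop = FALSE],
       test = panel[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx,
       train_fraction = train_fraction, seed = as.integer(seed))
}

#' Seeded k-fold assignment
#'
#' @param n number of rows.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return integer vector of fold labels 1..k; fold sizes differ by at
#'   most one and every row appears exactly once.
#' @export
make_folds <- function(n, k = 5L, seed = 2025L) {
  stopifnot(k >= 2L, k <= n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' K-fold cross-validation of a model family
#'
#' Fits the family on each training fold and scores the held-out fold
#' with [regression_metrics()]; every row is validated exactly once.
#'
#' @param data data frame with outcome and features.
#' @param formula model formula.
#' @param family one of [model_families()].
#' @param params hyperparameter overrides.
#' @param k number of folds (default 5).
#' @param seed integer seed controlling folds and fold fits.
#' @return list with \code{r2} (per-fold vector), \code{rmse},
#'   \code{mae}, \code{folds} (assignment vector).
#' @export
cross_validate <- function(data, formula, family = "xgboost",
                           params = list(), k = 5L, seed = 2025L) {
  folds <- make_folds(nrow(data), k, seed)
  r2 <- rmse <- mae <- numeric(k)
  for (f in seq_len(k)) {
    tr <- data[folds != f, , drop = FALSE]
    va <- data[folds == f, , drop = FALSE]
    m <- hse_model(formula, tr, family = family, params = params,
                   seed = seed + f)
    y <- stats::model.response(stats::model.frame(formula, va))
    met <- regression_metrics(y, predict(m, va))
    r2[f] <- met$r2; rmse[f] <- met$rmse; mae[f] <- met$mae
  }
  list(r2 = r2, rmse = rmse, mae = mae, folds = folds)
}

#' Random hyperparameter search by cross-validated R2
#'
#' Draws seeded candidates from a declared space, scores each by mean
#' k-fold cross-validated R2, and returns the best candidate with the
#' full trial log. Each space entry is either a vector of discrete
#' candidate values or a \code{list(min =, max =, log = FALSE)}
#' continuous range.
#'
#' @param data,formula,family,k as in [cross_validate()].
#' @param space named list describing per-parameter distributions.
#' @param budget number of random draws (>= 1).
#' @param seed integer seed; identical seed and budget reproduce the
#'   trial log exactly.
#' @return list with \code{best_params}, \code{best_score} and
#'   \code{trials} (data frame, one row per draw).
#' @export
random_search <- function(data, formula, family, space, budget = 20L,
                          k = 5L, seed = 2025L) {
  if (!is.list(space) || length(space) == 0L || is.null(names(space)))
    stop("`space` must be a non-empty named list")
  stopifnot(budget >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draws <- vector("list", budget)
  for (b in seq_len(budget)) {
    draws[[b]] <- lapply(space, function(sp) {
      if (is.list(sp)) {
        u <- stats::runif(1)
        if (isTRUE(sp$log)) exp(log(sp$min) + u * (log(sp$max) - log(sp$min)))
        else sp$min + u * (sp$max - sp$min)
      } else sp[[sample.int(length(sp), 1L)]]
    })
  }
  scores <- numeric(budget)
  for (b in seq_len(budget)) {
    cv <- cross_validate(data, formula, family = family,
                         params = draws[[b]], k = k, seed = seed)
    scores[b] <- mean(cv$r2)
  }
  trials <- cbind(do.call(rbind.data.frame, lapply(draws, as.data.frame)),
                  mean_cv_r2 = scores)
  best <- which.max(scores)
  list(best_params = draws[[best]], best_score = scores[best], trials = trials)
}

#' Benchmark the six model families on one split
#'
#' Fits every requested family on the identical seeded train/test split,
#' reports train/test R2, RMSE and MAE plus k-fold cross-validation
#' scores on the training rows, and sorts by test R2. A family that
#' fails to fit is recorded as failed and the rest proceed.
#'
#' @param panel data frame containing the outcome and features.
#' @param formula model formula (outcome on the left).
#' @param families character vector, subset of [model_families()].
#' @param params named list of per-family hyperparameter overrides.
#' @param train_fraction,seed split protocol (defaults 0.8 and 2025).
#' @param k folds for cross-validation (default 5); \code{k = 0} skips CV.
#' @return object of class \code{"hse_benchmark"}: list with
#'   \code{table} (metrics data frame sorted by test R2), \code{models}
#'   (named list of fitted \code{hse_model}s), \code{split},
#'   \code{cv_scores}, \code{failed}.
#' @export
run_benchmark <- function(panel, formula, families = model_families(),
                          params = list(), train_fraction = 0.8,
                          seed = 2025L, k = 5L) {
  families <- match.arg(families, model_families(), several.ok = TRUE)
  sp <- split_panel(panel, train_fraction, seed)
  y_tr <- stats::model.response(stats::model.frame(formula, sp$train))
  y_te <- stats::model.response(stats::model.frame(formula, sp$test))
  rows <- list(); models <- list(); cvs <- list(); failed <- character()
  for (fam in families) {
    fit <- tryCatch(
      hse_model(formula, sp$train, family = fam,
                params = if (!is.null(params[[fam]])) params[[fam]] else list(),
                seed = seed),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- c(failed, fam)
      warning("family '", fam, "' failed to fit: ", conditionMessage(fit))
      next
    }
    mt <- regression_metrics(y_tr, predict(fit, sp$train))
    me <- regression_metrics(y_te, predict(fit, sp$test))
    cv_r2 <- NA_real_
    if (k >= 2L) {
      cv <- cross_validate(sp$train, formula, family = fam,
                           params = if (!is.null(params[[fam]])) params[[fam]] else list(),
                           k = k, seed = seed)
      cvs[[fam]] <- cv$r2
      cv_r2 <- mean(cv$r2)
    }
    rows[[fam]] <- data.frame(
      family = fam, r2_train = mt$r2, r2_test = me$r2,
      rmse_train = mt$rmse, rmse_test = me$rmse,
      mae_train = mt$mae, mae_test = me$mae, cv_r2 = cv_r2)
    models[[fam]] <- fit
  }
  if (length(rows) == 0L) stop("every family failed to fit")
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$r2_test), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, models = models, split = sp,
                 cv_scores = cvs, failed = failed, formula = formula,
                 seed = as.integer(seed)),
            class = "hse_benchmark")
}

#' @export
print.hse_benchmark <- function(x, digits = 3, ...) {
  cat("Benchmark of", nrow(x$table), "model families",
      sprintf("(train %d / test %d, seed %d)\n",
              nrow(x$split$train), nrow(x$split$test), x$seed))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  if (length(x$failed)) cat("failed:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}
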