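# AdaBoost.R2 (Drucker 1997) for regression over rpart weak learners.
# Written in-package because no installed package provides boosting of
# this adaptive-reweighting form for continuous outcomes; tree fitting
# itself is delegated to rpart.

adaboost_r2_fit <- function(X, y, n_estimators = 100L, max_depth = 3L,
                            learning_rate = 1) {
  X <- as.data.frame(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 2L)
  w <- rep(1 / n, n)
  trees <- vector("list", n_estimators)
  betas <- numeric(n_estimators)
  dat <- cbind(X, .y = y)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 5,
                               minbucket = 2, xval = 0)
  m <- 0L
  for (t in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w * n, control = ctrl,
                        method = "anova")
    pred <- predict(fit, X)
    aerr <- abs(pred - y)
    denom <- max(aerr)
    if (denom == 0) {            # perfect learner: keep it, stop boosting
      m <- m + 1L; trees[[m]] <- fit; betas[m] <- 1e-10
      break
    }
    loss <- aerr / denom          # linear loss in [0, 1]
    ebar <- sum(w * loss)
    if (ebar >= 0.5) break        # weak-learner condition violated
    beta <- ebar / (1 - ebar)
    m <- m + 1L
    trees[[m]] <- fit
    betas[m] <- beta
    w <- w * beta^(learning_rate * (1 - loss))
    w <- w / sum(w)
  }
  if (m == 0L) {                  # fall back to a single tree
    trees[[1L]] <- rpart::rpart(.y ~ ., data = dat, control = ctrl,
                                method = "anova")
    betas[1L] <- 1e-10
    m <- 1L
  }
  list(trees = trees[seq_len(m)], betas = betas[seq_len(m)],
       features = names(X))
}

# Weighted-median combination of the weak predictions (log(1/beta) votes).
adaboost_r2_predict <- function(model, X) {
  X <- as.data.frame(X)[, model$features, drop = FALSE]
  P <- vapply(model$trees, function(tr) predict(tr, X), numeric(nrow(X)))
  if (is.null(dim(P))) P <- matrix(P, nrow = nrow(X))
  lw <- log(1 / model$betas)
  if (all(lw <= 0) || length(lw) == 1L) return(P[, 1L])
  apply(P, 1L, function(p) {
    o <- order(p)
    cw <- cumsum(lw[o])
    p[o][which(cw >= 0.5 * sum(lw))[1L]]
  })
}
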