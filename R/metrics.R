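#' Regression accuracy metrics
#'
#' Coefficient of determination, root mean square error and mean
#' absolute error, evaluated from their definitions:
#' \deqn{R^2 = 1 - \sum (y_i-\hat y_i)^2 / \sum (y_i-\bar y)^2}
#' \deqn{RMSE = \sqrt{\frac{1}{n}\sum (y_i-\hat y_i)^2},\quad
#'       MAE = \frac{1}{n}\sum |y_i-\hat y_i|}
#'
#' @param y actual values.
#' @param yhat predicted values (same length, n >= 2).
#' @return named list \code{r2}, \code{rmse}, \code{mae}. \code{RMSE >=
#'   MAE} always, with equality iff all absolute residuals are equal;
#'   the mean predictor scores \code{r2 = 0} on its own training data.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L,
            all(is.finite(y)), all(is.finite(yhat)))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("constant actual values: R2 undefined")
  res <- y - yhat
  list(r2 = 1 - sum(res^2) / ss_tot,
       rmse = sqrt(mean(res^2)),
       mae = mean(abs(res)))
}
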