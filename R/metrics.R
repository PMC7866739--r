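#' Regression performance metrics
#'
#' The three criteria used to judge model fit:
#' \deqn{RMSE = \sqrt{\sum_i (y_{est,i} - y_{act,i})^2 / n},}
#' \deqn{MBE = \frac{1}{n}\sum_i (y_{est,i} - y_{act,i}),}
#' \deqn{R^2 = 1 - \sum_i (y_{est,i} - y_{act,i})^2 / \sum_i (y_{act,i} -
#' \bar y)^2.}
#' They satisfy the identity `RMSE^2 = MBE^2 + var_n(residuals)` with the
#' population (divide-by-n) variance.
#'
#' @param y_act Actual values.
#' @param y_est Predicted values, same length (>= 2).
#' @return A list with elements `r2`, `rmse`, `mbe`.
#' @export
compute_metrics <- function(y_act, y_est) {
  y_act <- as.numeric(y_act); y_est <- as.numeric(y_est)
  if (length(y_act) != length(y_est)) stopf("y_act and y_est lengths differ")
  if (length(y_act) < 2) stopf("metrics need at least 2 observations")
  if (anyNA(y_act) || anyNA(y_est)) stopf("metric inputs must not contain NA")
  sst <- sum((y_act - mean(y_act))^2)
  if (sst == 0) stopf("R^2 is undefined: y_act has zero variance")
  resid <- y_est - y_act
  list(r2 = 1 - sum(resid^2) / sst,
       rmse = sqrt(mean(resid^2)),
       mbe = mean(resid))
}
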