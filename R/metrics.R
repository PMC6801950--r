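#' Forecast accuracy metrics
#'
#' Mean absolute error, root mean square error, mean absolute percentage
#' error (reported in percent) and Theil's inequality coefficient
#' `TIC = RMSE / (sqrt(mean(pred^2)) + sqrt(mean(actual^2)))`, which lies
#' in [0, 1] with 0 for a perfect forecast. Smaller is better for all four.
#'
#' @param pred,actual equal-length numeric vectors.
#' @param mape logical; MAPE requires all actuals to be non-zero.
#' @return A list of class `metric_report` with `MAE`, `RMSE`, `MAPE`
#'   (percent, `NA` if `mape = FALSE`), `TIC` and `N`.
#' @examples
#' forecast_metrics(c(110, 90), c(100, 100))
#' @export
forecast_metrics <- function(pred, actual, mape = TRUE) {
  pred <- as.numeric(pred); actual <- as.numeric(actual)
  if (length(pred) != length(actual) || length(pred) < 1)
    stop("`pred` and `actual` must be equal-length, non-empty", call. = FALSE)
  err <- pred - actual
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  mape_v <- NA_real_
  if (mape) {
    z <- which(actual == 0)
    if (length(z))
      stop("MAPE undefined: actual value is zero at index ", z[1],
           call. = FALSE)
    mape_v <- 100 * mean(abs(err / actual))
  }
  tic <- if (rmse == 0) 0 else
    rmse / (sqrt(mean(pred^2)) + sqrt(mean(actual^2)))
  structure(list(MAE = mae, RMSE = rmse, MAPE = mape_v, TIC = tic,
                 N = length(pred)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("MAE %.4f  RMSE %.4f  MAPE %s%%  TIC %.4f  (N = %d)\n",
              x$MAE, x$RMSE,
              if (is.na(x$MAPE)) "-" else sprintf("%.4f", x$MAPE),
              x$TIC, x$N))
  invisible(x)
}

#' Diebold-Mariano test of equal forecast accuracy
#'
#' Tests whether two forecast-error series have equal expected loss under
#' the absolute-error loss: with `D_i = |e_a,i| - |e_b,i|`, the statistic
#' is `DM = mean(D) / sqrt(s2 / T)` where `s2` is the sample variance of
#' `D`. Under the null of equal accuracy DM is asymptotically standard
#' normal; the p-value is two-sided. A positive DM means model `a` has the
#' larger absolute errors (model `b` more accurate).
#'
#' @param errors_a,errors_b equal-length forecast-error series, length
#'   >= 2.
#' @param loss only `"absolute"` is implemented.
#' @return A list of class `dm_result`: `dm_statistic`, `p_value`, `loss`,
#'   `N`.
#' @export
dm_test <- function(errors_a, errors_b, loss = c("absolute")) {
  loss <- match.arg(loss)
  errors_a <- as.numeric(errors_a); errors_b <- as.numeric(errors_b)
  if (length(errors_a) != length(errors_b) || length(errors_a) < 2)
    stop("error series must be equal-length with at least 2 points",
         call. = FALSE)
  D <- abs(errors_a) - abs(errors_b)
  s2 <- var(D)
  if (s2 <= 0)
    stop("degenerate loss differential: the two error series have ",
         "identical losses", call. = FALSE)
  dm <- mean(D) / sqrt(s2 / length(D))
  structure(list(dm_statistic = dm, p_value = 2 * pnorm(-abs(dm)),
                 loss = loss, N = length(D)),
            class = "dm_result")
}

#' @export
print.dm_result <- function(x, ...) {
  cat(sprintf("DM = %.4f, p = %.4g (%s loss, N = %d)\n",
              x$dm_statistic, x$p_value, x$loss, x$N))
  invisible(x)
}
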