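#' Chemometric figures of merit
#'
#' Computes the full calibration figure-of-merit suite for a spectra-to-Qi
#' model:
#'
#' * `r_squared` \eqn{= 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2}
#'   on the calibration pairs;
#' * `rmsec` — root mean square error on the calibration set;
#' * `rmsecv` — root mean square error of the cross-validated predictions;
#' * `rmsep` — root mean square error on the independent prediction set;
#' * `rep_percent` \eqn{= RMSEP / \bar y \times 100}, the prediction error
#'   relative to the mean reference value of the independent set;
#' * `rer` \eqn{= (y_{max} - y_{min}) / RMSEP}, the range error ratio.
#'
#' The conventional reading: `rer > 10` together with `rep_percent < 10`
#' marks a reliable calibration. When RMSEP is exactly zero, REP and RER are
#' reported as `Inf` with a warning.
#'
#' @param y_cal,yhat_cal Observed and predicted values, calibration set.
#' @param y_cv,yhat_cv Observed values and cross-validated predictions
#'   (optional).
#' @param y_test,yhat_test Observed and predicted values on the independent
#'   prediction set (optional).
#' @return A one-row `metrics_report` tibble with the six figures of merit
#'   plus auxiliary columns (`r_squared_cv`, `r_squared_test`, `n_cal`,
#'   `n_cv`, `n_test`, `y_mean_test`, `y_range_test`).
#' @export
compute_metrics <- function(y_cal, yhat_cal, y_cv = NULL, yhat_cv = NULL,
                            y_test = NULL, yhat_test = NULL) {
  pairlen <- function(a, b, what) {
    if (length(a) != length(b)) abort(sprintf("%s vectors differ in length", what))
  }
  pairlen(y_cal, yhat_cal, "calibration")
  r2 <- function(y, yhat) {
    tss <- sum((y - mean(y))^2)
    if (tss == 0) return(NA_real_)
    1 - sum((y - yhat)^2) / tss
  }
  rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

  out <- tibble::tibble(
    r_squared = r2(y_cal, yhat_cal),
    rmsec = rmse(y_cal, yhat_cal),
    rmsecv = NA_real_, rmsep = NA_real_,
    rep_percent = NA_real_, rer = NA_real_,
    r_squared_cv = NA_real_, r_squared_test = NA_real_,
    n_cal = length(y_cal), n_cv = 0L, n_test = 0L,
    y_mean_test = NA_real_, y_range_test = NA_real_
  )
  if (!is.null(y_cv)) {
    pairlen(y_cv, yhat_cv, "cross-validation")
    out$rmsecv <- rmse(y_cv, yhat_cv)
    out$r_squared_cv <- r2(y_cv, yhat_cv)
    out$n_cv <- length(y_cv)
  }
  if (!is.null(y_test)) {
    pairlen(y_test, yhat_test, "prediction")
    out$rmsep <- rmse(y_test, yhat_test)
    out$r_squared_test <- r2(y_test, yhat_test)
    out$n_test <- length(y_test)
    out$y_mean_test <- mean(y_test)
    out$y_range_test <- diff(range(y_test))
    if (out$rmsep == 0) {
      warn("RMSEP is exactly 0; REP and RER reported as infinite")
      out$rep_percent <- Inf
      out$rer <- Inf
    } else {
      out$rep_percent <- out$rmsep / out$y_mean_test * 100
      out$rer <- out$y_range_test / out$rmsep
    }
  }
  class(out) <- c("metrics_report", class(out))
  out
}

#' Combine per-cultivar prediction metrics
#'
#' Builds the "Combined" row of a prediction-error table: the arithmetic
#' mean of the per-cultivar RMSEP, REP and RER, rounded half-up to the
#' table's conventional precision (3, 2 and 1 decimals respectively).
#'
#' @param reports A data frame with one row per cultivar and columns
#'   `rmsep`, `rep_percent`, `rer` (e.g. stacked `metrics_report` rows).
#' @return A one-row tibble with the combined, rounded values.
#' @examples
#' aggregate_combined(tibble::tibble(rmsep = c(0.256, 0.266),
#'                                   rep_percent = c(8.12, 8.75),
#'                                   rer = c(10.6, 9.8)))
#' @export
aggregate_combined <- function(reports) {
  check_columns(reports, c("rmsep", "rep_percent", "rer"), "metric reports")
  if (nrow(reports) < 2) abort("need >= 2 per-cultivar reports to combine")
  tibble::tibble(
    cultivar = "Combined",
    rmsep = round_half_up(mean(reports$rmsep), 3),
    rep_percent = round_half_up(mean(reports$rep_percent), 2),
    rer = round_half_up(mean(reports$rer), 1)
  )
}

#' Side-by-side comparison of two calibration models
#'
#' Lines up the figure-of-merit rows of two models evaluated on identical
#' splits and flags, per metric, which model wins (higher is better for
#' `r_squared`, `r_squared_cv`, `r_squared_test` and `rer`; lower is better
#' for the error metrics).
#'
#' @param report_a,report_b One-row `metrics_report` tibbles.
#' @param labels Model names, length 2.
#' @return A tibble with columns `metric`, the two model values, and
#'   `winner` (one of the labels or `"tie"`).
#' @export
compare_models <- function(report_a, report_b, labels = c("PLSR", "ANN")) {
  sizes <- c("n_cal", "n_cv", "n_test")
  if (!identical(as.list(report_a[sizes]), as.list(report_b[sizes]))) {
    abort("reports were not computed on identical splits (sample counts differ)")
  }
  metrics <- c(r_squared = 1, rmsec = -1, rmsecv = -1, rmsep = -1,
               rep_percent = -1, rer = 1, r_squared_cv = 1, r_squared_test = 1)
  rows <- purrr::imap(metrics, function(dir, m) {
    a <- report_a[[m]]; b <- report_b[[m]]
    winner <- if (is.na(a) || is.na(b) || a == b) "tie"
              else if ((a - b) * dir > 0) labels[1] else labels[2]
    tibble::tibble(metric = m, !!labels[1] := a, !!labels[2] := b,
                   winner = winner)
  })
  dplyr::bind_rows(rows)
}

#' Predicted-vs-observed plot for a metrics report
#'
#' @param y,yhat Observed and predicted values (e.g. the independent set).
#' @param label Plot title.
#' @return A ggplot object.
#' @export
plot_predictions <- function(y, yhat, label = "Predicted vs observed Qi") {
  df <- tibble::tibble(observed = y, predicted = yhat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Observed", y = "Predicted", title = label) +
    ggplot2::theme_minimal()
}
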