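#' Fit a storage-degradation polynomial
#'
#' Fits Qi against storage time (months) by ordinary least squares, degree 1
#' (linear) or 2 (quadratic). Coefficients are reported in the shelf-life
#' convention \eqn{Qi = a t^2 - b t + c}: `a` is the curvature (0 for a
#' linear fit), `b` the negated linear slope (so a positive `b` means early
#' decline), and `c` the intercept, the quality index of fresh fruit.
#'
#' @param data A data frame with the time and response columns, or `NULL`
#'   when `t` and `qi` are given directly.
#' @param t,qi Column names (when `data` is supplied) or numeric vectors.
#' @param degree 1 or 2.
#' @return A `qi_degradation_fit` with elements `degree`, `a`, `b`, `c`,
#'   `r_squared`, `rss`, `n`, `aic`, and the underlying `lm` fit.
#' @examples
#' months <- 0:12
#' qi <- -0.0007 * months^2 - 0.0102 * months + 0.9719
#' fit <- fit_degradation(t = months, qi = qi, degree = 2)
#' predict(fit, t = 0)
#' @export
fit_degradation <- function(data = NULL, t = "month", qi = "qi", degree = 2) {
  if (!degree %in% c(1, 2)) abort("`degree` must be 1 or 2")
  if (!is.null(data)) {
    check_columns(data, c(t, qi), "degradation data")
    tt <- data[[t]]
    yy <- data[[qi]]
  } else {
    tt <- t
    yy <- qi
  }
  check_finite(tt, "t")
  check_finite(yy, "qi")
  n <- length(tt)
  if (length(yy) != n) abort("t and qi lengths differ")
  if (n < degree + 2) abort(sprintf("need at least %d points for degree %d", degree + 2, degree))
  if (length(unique(tt)) < degree + 1) abort("singular design: too few distinct time points")

  fit <- if (degree == 2) lm(yy ~ tt + I(tt^2)) else lm(yy ~ tt)
  cf <- coef(fit)
  if (any(!is.finite(cf))) abort("singular design: coefficients not estimable")
  res <- unname(fit$residuals)
  rss <- sum(res^2)
  tss <- sum((yy - mean(yy))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  out <- structure(list(
    degree = degree,
    a = if (degree == 2) unname(cf[["I(tt^2)"]]) else 0,
    b = -unname(cf[["tt"]]),
    c = unname(cf[["(Intercept)"]]),
    r_squared = r2,
    rss = rss,
    n = n,
    lm_fit = fit,
    t = tt,
    qi = yy
  ), class = "qi_degradation_fit")
  out$aic <- tryCatch(degradation_aic(out), error = function(e) NA_real_)
  out
}

#' Evaluate a degradation fit at new times
#'
#' Evaluates \eqn{Qi = a t^2 - b t + c}. Values are not clipped to `[0, 1]`;
#' extrapolation is the caller's responsibility.
#'
#' @param object A `qi_degradation_fit`.
#' @param t Months at which to predict.
#' @param ... Unused.
#' @return Numeric vector of predicted Qi.
#' @export
predict.qi_degradation_fit <- function(object, t, ...) {
  check_finite(t, "t")
  object$a * t^2 - object$b * t + object$c
}

#' Profile-Gaussian AIC of a degradation fit
#'
#' AIC under the profiled Gaussian likelihood,
#' \eqn{AIC = n \log(RSS/n) + 2k}, with `k` counting the polynomial
#' coefficients plus the error variance. Undefined (error) when the fit is
#' exact (RSS = 0).
#'
#' @param fit A `qi_degradation_fit`.
#' @return AIC, a scalar.
#' @export
degradation_aic <- function(fit) {
  if (!inherits(fit, "qi_degradation_fit")) abort("`fit` must be a qi_degradation_fit")
  if (fit$rss <= 0) abort("AIC undefined for a perfect fit (RSS = 0)")
  k <- (fit$degree + 1) + 1
  fit$n * log(fit$rss / fit$n) + 2 * k
}

#' Compare linear and quadratic degradation models
#'
#' Fits both polynomials to one Qi-vs-time series and compares them by AIC
#' and the extra-sum-of-squares (nested) F-test:
#' \eqn{F = (RSS_{lin} - RSS_{quad}) / (RSS_{quad} / (n - 3))}, with the
#' p-value from the `F(1, n - 3)` distribution.
#'
#' @inheritParams fit_degradation
#' @return A `qi_model_comparison` with both fits, `delta_aic`
#'   (quadratic minus linear), `f_statistic` and `p_value`.
#' @export
compare_degradation_models <- function(data = NULL, t = "month", qi = "qi") {
  lin <- fit_degradation(data, t, qi, degree = 1)
  quad <- fit_degradation(data, t, qi, degree = 2)
  n <- quad$n
  if (n < 4) abort("need at least 4 points to compare nested models")
  if (quad$rss <= 0) abort("degenerate test: quadratic fit is exact (RSS = 0)")
  f_stat <- max(0, (lin$rss - quad$rss) / (quad$rss / (n - 3)))
  p_val <- pf(f_stat, 1, n - 3, lower.tail = FALSE)
  structure(list(
    linear = lin,
    quadratic = quad,
    delta_aic = quad$aic - lin$aic,
    f_statistic = f_stat,
    p_value = p_val
  ), class = "qi_model_comparison")
}

#' Storage time at which predicted quality crosses a threshold
#'
#' Solves \eqn{a t^2 - b t + c = q} for the earliest non-negative root, a
#' shelf-life helper. Returns `NA` when the fitted curve never reaches the
#' threshold.
#'
#' @param fit A `qi_degradation_fit`.
#' @param threshold Qi level to cross.
#' @return Months (scalar), or `NA_real_`.
#' @export
shelf_life_at <- function(fit, threshold) {
  if (!inherits(fit, "qi_degradation_fit")) abort("`fit` must be a qi_degradation_fit")
  check_finite(threshold, "threshold")
  a <- fit$a; b <- -fit$b; c0 <- fit$c - threshold
  if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) return(NA_real_)
    root <- -c0 / b
    return(if (root >= 0) root else NA_real_)
  }
  disc <- b^2 - 4 * a * c0
  if (disc < 0) return(NA_real_)
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  roots <- roots[roots >= 0]
  if (length(roots) == 0) NA_real_ else roots[1]
}

#' @export
print.qi_degradation_fit <- function(x, ...) {
  cat(sprintf("Degradation fit (degree %d): Qi = %.6g*t^2 - %.6g*t + %.6g\n",
              x$degree, x$a, x$b, x$c))
  cat(sprintf("  n = %d, R^2 = %.4f, RSS = %.6g, AIC = %.4g\n",
              x$n, x$r_squared, x$rss, x$aic))
  invisible(x)
}

#' @export
print.qi_model_comparison <- function(x, ...) {
  cat("Linear vs quadratic degradation model\n")
  cat(sprintf("  AIC: linear %.4g, quadratic %.4g (delta %.4g)\n",
              x$linear$aic, x$quadratic$aic, x$delta_aic))
  cat(sprintf("  Nested F(1, %d) = %.4g, p = %.4g\n",
              x$quadratic$n - 3, x$f_statistic, x$p_value))
  invisible(x)
}

#' @describeIn fit_degradation Tidy the coefficients of a degradation fit.
#' @param x A `qi_degradation_fit`.
#' @param ... Unused.
#' @export
tidy.qi_degradation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c"),
    estimate = c(x$a, x$b, x$c),
    description = c("curvature (month^-2)",
                    "negated slope (month^-1)",
                    "intercept: Qi at t = 0")
  )
}

#' @describeIn fit_degradation One-row fit summary.
#' @export
glance.qi_degradation_fit <- function(x, ...) {
  tibble::tibble(degree = x$degree, r_squared = x$r_squared, rss = x$rss,
                 aic = x$aic, n = x$n)
}

#' @export
tidy.qi_model_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$linear), model = "linear", .before = 1),
    dplyr::mutate(glance(x$quadratic), model = "quadratic", .before = 1)
  )
}

#' @export
glance.qi_model_comparison <- function(x, ...) {
  tibble::tibble(delta_aic = x$delta_aic, f_statistic = x$f_statistic,
                 p_value = x$p_value,
                 preferred = if (x$delta_aic < 0) "quadratic" else "linear")
}

#' Plot a degradation fit
#'
#' Observed Qi-vs-month points with the fitted polynomial overlaid.
#'
#' @param object A `qi_degradation_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qi_degradation_fit <- function(object, ...) {
  obs <- tibble::tibble(t = object$t, qi = object$qi)
  grid <- tibble::tibble(t = seq(min(obs$t), max(obs$t), length.out = 200))
  grid$qi <- predict(object, grid$t)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t, y = .data$qi)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(x = "Storage time (months)", y = "Quality index (Qi)",
                  title = sprintf("Degree-%d degradation fit", object$degree)) +
    ggplot2::theme_minimal()
}
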