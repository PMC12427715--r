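#' CIELAB colour derivatives
#'
#' Colour derivatives used to track browning and colour drift of stored date
#' fruit: chroma, hue angle, the browning index (BI) and the total colour
#' difference (Delta E) are computed from CIELAB readings (`L*`, `a*`, `b*`)
#' as produced by a colorimeter.
#'
#' * `chroma()` is the radial colour intensity, \eqn{(a^{*2} + b^{*2})^{1/2}}.
#' * `hue_angle()` is the quadrant-aware arctangent of \eqn{b^*/a^*}, reported
#'   in degrees in `[0, 360)`. The single-argument arctangent is
#'   quadrant-ambiguous, so the two-argument convention is used.
#' * `browning_index()` follows the standard chromaticity construction
#'   \eqn{x = (a^* + 1.75 L^*) / (5.645 L^* + a^* - 3.012 b^*)},
#'   \eqn{BI = 100 (x - 0.31) / 0.17}. The denominator must be positive;
#'   degenerate colours raise an error rather than returning infinities.
#' * `delta_e()` is the Euclidean CIELAB distance between a sample and its
#'   reference \eqn{(L_0^*, a_0^*, b_0^*)}. With `strict = TRUE` the
#'   difference is computed with a negated \eqn{(b_0^*-b^*)^2} term (an
#'   audit mode for one published variant of the formula); a negative
#'   radicand is then a domain error.
#'
#' All functions are vectorized over their inputs.
#'
#' @param a_star,b_star CIELAB red-green and yellow-blue coordinates.
#' @param L_star CIELAB lightness, `>= 0`.
#' @return A numeric vector.
#' @examples
#' chroma(3, 4)
#' hue_angle(0, 1)
#' browning_index(40, 10, 20)
#' delta_e(50, 0, 0, 53, 4, 12)
#' @name colorimetry
NULL

#' @rdname colorimetry
#' @export
chroma <- function(a_star, b_star) {
  check_finite(a_star, "a_star")
  check_finite(b_star, "b_star")
  sqrt(a_star^2 + b_star^2)
}

#' @rdname colorimetry
#' @export
hue_angle <- function(a_star, b_star) {
  check_finite(a_star, "a_star")
  check_finite(b_star, "b_star")
  if (any(a_star == 0 & b_star == 0)) {
    abort("hue angle is undefined at a* = b* = 0")
  }
  (atan2(b_star, a_star) * 180 / pi) %% 360
}

#' @rdname colorimetry
#' @export
browning_index <- function(L_star, a_star, b_star) {
  check_finite(L_star, "L_star")
  check_finite(a_star, "a_star")
  check_finite(b_star, "b_star")
  if (any(L_star < 0)) abort("`L_star` must be >= 0")
  denom <- 5.645 * L_star + a_star - 3.012 * b_star
  if (any(denom <= 0)) {
    abort("degenerate colour: 5.645*L* + a* - 3.012*b* must be positive")
  }
  x <- (a_star + 1.75 * L_star) / denom
  100 * (x - 0.31) / 0.17
}

#' @rdname colorimetry
#' @param L0_star,a0_star,b0_star Reference CIELAB reading.
#' @param strict If `TRUE`, negate the b-axis squared term before taking the
#'   square root (audit mode); a negative radicand is then an error.
#' @export
delta_e <- function(L0_star, a0_star, b0_star, L_star, a_star, b_star,
                    strict = FALSE) {
  for (v in list(L0_star, a0_star, b0_star, L_star, a_star, b_star)) {
    check_finite(v, "colour reading")
  }
  dL2 <- (L0_star - L_star)^2
  da2 <- (a0_star - a_star)^2
  db2 <- (b0_star - b_star)^2
  radicand <- if (strict) dL2 + da2 - db2 else dL2 + da2 + db2
  if (strict && any(radicand < 0)) {
    abort("strict-mode radicand is negative; no real colour difference exists")
  }
  sqrt(radicand)
}

#' Colour derivatives for a table of CIELAB readings
#'
#' Adds `chroma`, `hue_angle` and `browning_index` columns to a colour table
#' with columns `L_star`, `a_star`, `b_star`; when reference columns
#' `L0_star`, `a0_star`, `b0_star` are also present, a `delta_e` column is
#' added as well.
#'
#' @param df A data frame of CIELAB readings.
#' @inheritParams delta_e
#' @return A tibble: the input plus the derivative columns.
#' @export
color_derivatives <- function(df, strict = FALSE) {
  check_columns(df, c("L_star", "a_star", "b_star"), "colour table")
  out <- tibble::as_tibble(df)
  out$chroma <- chroma(out$a_star, out$b_star)
  out$hue_angle <- hue_angle(out$a_star, out$b_star)
  out$browning_index <- browning_index(out$L_star, out$a_star, out$b_star)
  if (all(c("L0_star", "a0_star", "b0_star") %in% names(out))) {
    out$delta_e <- delta_e(out$L0_star, out$a0_star, out$b0_star,
                           out$L_star, out$a_star, out$b_star,
                           strict = strict)
  }
  out
}
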