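#' Wide-format spectra tables
#'
#' Spectra live in wide tibbles: identifier and design columns
#' (`sample_id`, `replicate_group_id`, `cultivar`, `moisture_group`,
#' `temperature_C`, `packaging`, `month`, ...) followed by one numeric
#' column per wavelength named `wl_0411` ... `wl_0990` (nm, zero-padded to
#' four digits). The grid must be uniform; the instrument samples every
#' 3 nm. A `spectra_mode` attribute tracks the representation
#' (`"reflectance_percent"`, `"absorbance"` or `"d2_absorbance"`); helpers
#' infer `"reflectance_percent"` when the attribute is absent.
#'
#' @param df A spectra tibble.
#' @return `spectra_wavelengths()`: numeric wavelengths (nm).
#'   `spectra_matrix()`: the samples-by-wavelengths numeric matrix.
#'   `spectra_mode()`: the mode string.
#' @name spectra_table
NULL

wl_cols <- function(df) grep("^wl_[0-9]{4}$", names(df), value = TRUE)

#' @rdname spectra_table
#' @export
spectra_wavelengths <- function(df) {
  cols <- wl_cols(df)
  if (length(cols) == 0) abort("no wavelength columns (wl_####) found")
  as.numeric(sub("^wl_", "", cols))
}

#' @rdname spectra_table
#' @export
spectra_matrix <- function(df) {
  cols <- wl_cols(df)
  m <- as.matrix(df[, cols, drop = FALSE])
  colnames(m) <- cols
  storage.mode(m) <- "double"
  m
}

#' @rdname spectra_table
#' @export
spectra_mode <- function(df) {
  attr(df, "spectra_mode") %||% "reflectance_percent"
}

set_spectra_mode <- function(df, mode) {
  attr(df, "spectra_mode") <- mode
  df
}

# Replace the wavelength block of `df` with matrix `m` (columns named wl_####)
set_spectra_values <- function(df, m, mode = spectra_mode(df)) {
  meta <- df[, setdiff(names(df), wl_cols(df)), drop = FALSE]
  out <- dplyr::bind_cols(tibble::as_tibble(meta), tibble::as_tibble(m))
  set_spectra_mode(out, mode)
}

wl_names <- function(wavelengths) sprintf("wl_%04d", round(wavelengths))

check_uniform_grid <- function(wavelengths) {
  if (length(wavelengths) > 1) {
    steps <- diff(wavelengths)
    if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-9) {
      abort("wavelength grid must be strictly increasing and uniform")
    }
  }
  invisible(wavelengths)
}

#' Restrict spectra to a wavelength window
#'
#' Keeps the grid points within `[lo_nm, hi_nm]`. The modeling window for
#' VIS-NIR date-fruit spectra is 410-990 nm: the instrument's full 285-1200
#' nm range carries unstable UV and long-NIR edges that are excluded before
#' calibration.
#'
#' @param df Spectra tibble.
#' @param lo_nm,hi_nm Window bounds in nm (inclusive).
#' @return Spectra tibble restricted to the window.
#' @export
window_spectra <- function(df, lo_nm = 410, hi_nm = 990) {
  wl <- spectra_wavelengths(df)
  check_uniform_grid(wl)
  keep <- wl >= lo_nm & wl <= hi_nm
  if (!any(keep)) abort(sprintf("no grid points inside [%g, %g] nm", lo_nm, hi_nm))
  drop_cols <- wl_cols(df)[!keep]
  out <- df[, setdiff(names(df), drop_cols), drop = FALSE]
  set_spectra_mode(tibble::as_tibble(out), spectra_mode(df))
}

#' Convert percent reflectance to absorbance
#'
#' The chemometric bridge \eqn{A = \log_{10}(100 / R\%)} (equivalently
#' \eqn{\log_{10}(1/R)} with R as a fraction). Reflectance must be strictly
#' positive.
#'
#' @param df Spectra tibble in `reflectance_percent` mode.
#' @return Spectra tibble in `absorbance` mode.
#' @export
reflectance_to_absorbance <- function(df) {
  if (spectra_mode(df) != "reflectance_percent") {
    abort(sprintf("expected reflectance_percent spectra, got %s", spectra_mode(df)))
  }
  m <- spectra_matrix(df)
  if (any(m <= 0)) abort("reflectance must be > 0 to convert to absorbance")
  set_spectra_values(df, log10(100 / m), mode = "absorbance")
}

#' Multiplicative scatter correction
#'
#' Each absorbance spectrum `x` is regressed on a reference spectrum `r`
#' (`x ~ alpha + beta * r`); the corrected spectrum is `(x - alpha) / beta`.
#' The reference defaults to the column mean of the supplied (training)
#' matrix and is attached to the result (attribute `msc_reference`) so the
#' same correction can be replayed on held-out data.
#'
#' @param df Spectra tibble in `absorbance` mode.
#' @param reference Optional reference spectrum (numeric vector, one value
#'   per wavelength). Required when `df` has a single row.
#' @return Corrected spectra tibble, with the reference in attribute
#'   `msc_reference`.
#' @export
msc_correct <- function(df, reference = NULL) {
  if (spectra_mode(df) != "absorbance") {
    abort(sprintf("MSC expects absorbance spectra, got %s", spectra_mode(df)))
  }
  m <- spectra_matrix(df)
  if (is.null(reference)) {
    if (nrow(m) < 2) abort("need >= 2 spectra (or an explicit reference) for MSC")
    reference <- colMeans(m)
  }
  if (length(reference) != ncol(m)) abort("reference length must match the wavelength grid")
  r <- reference - mean(reference)
  denom <- sum(r^2)
  if (denom < 1e-24) abort("flat MSC reference spectrum")
  corrected <- t(apply(m, 1, function(x) {
    beta <- sum((x - mean(x)) * r) / denom
    if (abs(beta) < 1e-12) abort("flat spectrum: MSC slope ~ 0")
    alpha <- mean(x) - beta * mean(reference)
    (x - alpha) / beta
  }))
  colnames(corrected) <- wl_cols(df)
  out <- set_spectra_values(df, corrected, mode = "absorbance")
  attr(out, "msc_reference") <- reference
  out
}

# Savitzky-Golay convolution weights for the d-th derivative:
# local polynomial least squares on offsets -h..h, scaled by d! / delta^d.
sg_coefficients <- function(window_points, poly_order = 2, deriv = 2, delta = 1) {
  if (window_points %% 2 == 0) abort("SG window must be odd")
  if (window_points < 5) abort("SG window must be >= 5 points")
  if (poly_order < deriv) abort("poly_order must be >= derivative order")
  if (poly_order >= window_points) abort("poly_order must be < window size")
  h <- (window_points - 1) / 2
  j <- -h:h
  V <- outer(j, 0:poly_order, `^`)
  C <- solve(crossprod(V), t(V))
  C[deriv + 1, ] * factorial(deriv) / delta^deriv
}

#' Savitzky-Golay second derivative
#'
#' Estimates the second derivative of each spectrum with respect to
#' wavelength by local least-squares polynomial fits (degree `poly_order`,
#' `window_points` grid points). Output units are value per nm squared. The
#' output grid is trimmed to the interior region where the window fits
#' entirely, so every reported point is a true local fit (no edge padding).
#'
#' Derivative spectra resolve overlapped absorption bands and remove
#' baseline offset and slope, which is why calibration uses the second
#' derivative of absorbance rather than the raw spectra.
#'
#' @param df Spectra tibble (typically `absorbance` mode).
#' @param window_points Odd window size, `>= 5`; default 13 points
#'   (about 39 nm on the 3 nm grid).
#' @param poly_order Local polynomial degree, `>= 2`; default 2.
#' @return Spectra tibble in `d2_absorbance` mode on the trimmed grid.
#' @export
savitzky_golay_d2 <- function(df, window_points = 13, poly_order = 2) {
  wl <- spectra_wavelengths(df)
  check_uniform_grid(wl)
  p <- length(wl)
  if (window_points > p) abort("SG window exceeds spectrum length")
  delta <- if (p > 1) wl[2] - wl[1] else 1
  w <- sg_coefficients(window_points, poly_order, deriv = 2, delta = delta)
  h <- (window_points - 1) / 2
  m <- spectra_matrix(df)
  valid <- (h + 1):(p - h)
  d2 <- matrix(0, nrow(m), length(valid))
  for (i in seq_along(valid)) {
    block <- m[, (valid[i] - h):(valid[i] + h), drop = FALSE]
    d2[, i] <- block %*% w
  }
  colnames(d2) <- wl_names(wl[valid])
  out <- df[, setdiff(names(df), wl_cols(df)), drop = FALSE]
  out <- dplyr::bind_cols(tibble::as_tibble(out), tibble::as_tibble(d2))
  set_spectra_mode(out, "d2_absorbance")
}

#' Fit and apply the spectral preprocessing pipeline
#'
#' The calibration representation is built in a fixed order:
#' window (410-990 nm) -> absorbance conversion -> multiplicative scatter
#' correction -> Savitzky-Golay second derivative. All stateful pieces (the
#' MSC reference) are fit on the supplied (training) spectra only, and the
#' returned `spectra_pipeline` replays the identical transform on held-out
#' data, which prevents information leaking from test spectra into the
#' preprocessing.
#'
#' @param train Spectra tibble in `reflectance_percent` mode (training rows).
#' @param lo_nm,hi_nm Wavelength window.
#' @param sg_window,sg_poly_order Savitzky-Golay settings.
#' @return A `spectra_pipeline` object.
#' @export
fit_spectra_pipeline <- function(train, lo_nm = 410, hi_nm = 990,
                                 sg_window = 13, sg_poly_order = 2) {
  windowed <- window_spectra(train, lo_nm, hi_nm)
  absorb <- reflectance_to_absorbance(windowed)
  msc <- msc_correct(absorb)
  reference <- attr(msc, "msc_reference")
  structure(list(
    lo_nm = lo_nm, hi_nm = hi_nm,
    sg_window = sg_window, sg_poly_order = sg_poly_order,
    msc_reference = reference,
    wavelengths_in = spectra_wavelengths(windowed)
  ), class = "spectra_pipeline")
}

#' @rdname fit_spectra_pipeline
#' @param pipeline A fitted `spectra_pipeline`.
#' @param df Spectra tibble in `reflectance_percent` mode.
#' @export
apply_spectra_pipeline <- function(pipeline, df) {
  if (!inherits(pipeline, "spectra_pipeline")) abort("`pipeline` must be a spectra_pipeline")
  windowed <- window_spectra(df, pipeline$lo_nm, pipeline$hi_nm)
  wl <- spectra_wavelengths(windowed)
  if (length(wl) != length(pipeline$wavelengths_in) ||
      max(abs(wl - pipeline$wavelengths_in)) > 1e-9) {
    abort("wavelength grid does not match the grid the pipeline was fit on")
  }
  absorb <- reflectance_to_absorbance(windowed)
  msc <- msc_correct(absorb, reference = pipeline$msc_reference)
  savitzky_golay_d2(msc, pipeline$sg_window, pipeline$sg_poly_order)
}

#' @rdname fit_spectra_pipeline
#' @export
preprocess_spectra <- function(train, df = train, lo_nm = 410, hi_nm = 990,
                               sg_window = 13, sg_poly_order = 2) {
  pipeline <- fit_spectra_pipeline(train, lo_nm, hi_nm, sg_window, sg_poly_order)
  apply_spectra_pipeline(pipeline, df)
}

#' @export
print.spectra_pipeline <- function(x, ...) {
  cat(sprintf(paste0("Spectral preprocessing pipeline: window [%g, %g] nm -> ",
                     "absorbance -> MSC -> SG d2 (window %d, order %d)\n"),
              x$lo_nm, x$hi_nm, x$sg_window, x$sg_poly_order))
  cat(sprintf("  grid: %d points, MSC reference frozen on training data\n",
              length(x$wavelengths_in)))
  invisible(x)
}

#' Select a Savitzky-Golay window by cross-validated error
#'
#' Grid search over candidate SG window sizes: for each candidate the
#' pipeline is refit, a PLSR model is cross-validated on the training rows,
#' and the window minimizing RMSECV (at that window's selected latent-
#' variable count) wins. Off by default in the pipeline; the fixed default
#' window is 13 points.
#'
#' @param train Reflectance spectra tibble (training rows) with a
#'   `replicate_group_id` column.
#' @param y Response vector aligned with `train` rows.
#' @param candidates Odd window sizes to try.
#' @param max_components,k_folds,seed Passed to [cross_validate_lv()].
#' @param lo_nm,hi_nm Wavelength window.
#' @return A tibble with one row per candidate (`sg_window`, `rmsecv`,
#'   `n_components`), best first.
#' @export
select_sg_window <- function(train, y, candidates = c(7, 9, 11, 13, 17, 21),
                             max_components = 10, k_folds = 10, seed = 1,
                             lo_nm = 410, hi_nm = 990) {
  rows <- purrr::map(candidates, function(w) {
    pp <- preprocess_spectra(train, lo_nm = lo_nm, hi_nm = hi_nm, sg_window = w)
    cv <- cross_validate_lv(spectra_matrix(pp), y,
                            groups = pp$replicate_group_id,
                            max_components = max_components,
                            k_folds = k_folds, seed = seed)
    tibble::tibble(sg_window = w, rmsecv = min(cv$per_component$rmsecv),
                   n_components = cv$selected)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$rmsecv)
}

#' Plot mean spectra by a grouping column
#'
#' @param df Spectra tibble.
#' @param colour_by Metadata column used to colour the mean curves.
#' @return A ggplot object.
#' @export
plot_spectra <- function(df, colour_by = "month") {
  check_columns(df, colour_by, "spectra table")
  long <- tidyr::pivot_longer(df, cols = dplyr::all_of(wl_cols(df)),
                              names_to = "wavelength", values_to = "value")
  long$wavelength <- as.numeric(sub("^wl_", "", long$wavelength))
  means <- dplyr::summarise(
    dplyr::group_by(long, .data$wavelength, group = factor(.data[[colour_by]])),
    value = mean(.data$value), .groups = "drop")
  ylab <- switch(spectra_mode(df),
                 reflectance_percent = "Reflectance (%)",
                 absorbance = "Absorbance",
                 d2_absorbance = "d2 absorbance (nm^-2)")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$wavelength, y = .data$value,
                                      colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = ylab, colour = colour_by) +
    ggplot2::theme_minimal()
}
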