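# Small in-code fixtures shared across test files.

# A minimal wide spectra tibble in reflectance-percent mode.
make_spectra <- function(values, wavelengths = seq(411, 990, 3),
                         mode = "reflectance_percent", meta = NULL) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  colnames(values) <- sprintf("wl_%04d", wavelengths)
  meta <- meta %||% tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(nrow(values))),
    replicate_group_id = sprintf("g%03d", seq_len(nrow(values))))
  out <- dplyr::bind_cols(meta, tibble::as_tibble(values))
  attr(out, "spectra_mode") <- mode
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quality records with two attributes spanning known ranges.
make_quality_records <- function(n = 6) {
  tibble::tibble(
    sample_id = sprintf("q%02d", seq_len(n)),
    good = seq(0, 10, length.out = n),
    bad = seq(100, 200, length.out = n)
  )
}

# Brute-force leave-one-out PLSR RMSECV oracle (refits per left-out sample).
loo_rmsecv_oracle <- function(X, y, n_components) {
  errs <- vapply(seq_len(nrow(X)), function(i) {
    m <- plsr_fit(X[-i, , drop = FALSE], y[-i], n_components = n_components)
    (y[i] - predict(m, X[i, , drop = FALSE]))^2
  }, numeric(1))
  sqrt(mean(errs))
}
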