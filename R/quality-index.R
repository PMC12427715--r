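#' Default quality-index attribute set and directions
#'
#' The composite quality index averages 14 attributes: 7 physicochemical
#' (moisture content, water activity, total soluble solids, browning index,
#' total colour difference, pH, hardness) and 7 sensory hedonic scores.
#' Sensory scores are better when higher; browning index and colour drift are
#' better when lower. Directions for aw, pH, TSS and hardness are not fixed
#' by the science (drift in either direction degrades quality); the defaults
#' below treat moisture, aw, TSS and hardness retention as
#' `higher_is_better` and BI/Delta E as `lower_is_better`, and every
#' direction is overridable when building the normalization spec.
#'
#' @return `qi_default_attributes()`: character vector of 14 attribute names.
#'   `qi_default_directions()`: named character vector of directions.
#' @export
qi_default_attributes <- function() {
  c("moisture", "aw", "tss", "bi", "delta_e", "ph", "hardness",
    "sens_texture", "sens_taste", "sens_hardness", "sens_color",
    "sens_adhesion", "sens_peelability", "sens_overall")
}

#' @rdname qi_default_attributes
#' @export
qi_default_directions <- function() {
  c(moisture = "higher_is_better",
    aw = "higher_is_better",
    tss = "higher_is_better",
    bi = "lower_is_better",
    delta_e = "lower_is_better",
    ph = "higher_is_better",
    hardness = "higher_is_better",
    tvc_log = "lower_is_better",
    ye_log = "lower_is_better",
    sens_texture = "higher_is_better",
    sens_taste = "higher_is_better",
    sens_hardness = "higher_is_better",
    sens_color = "higher_is_better",
    sens_adhesion = "higher_is_better",
    sens_peelability = "higher_is_better",
    sens_overall = "higher_is_better")
}

#' Build a min-max normalization spec from quality records
#'
#' Scans a quality-record table and records, per attribute, the dataset-wide
#' minimum and maximum and the quality direction. The spec is frozen on
#' (training) data and re-applied to later data, so calibration and
#' prediction share one scale.
#'
#' @param records A data frame with one row per sample and one numeric column
#'   per attribute.
#' @param attributes Character vector of attribute columns to include.
#' @param directions Named character vector mapping attributes to
#'   `"higher_is_better"` or `"lower_is_better"`; defaults from
#'   [qi_default_directions()] for known names.
#' @return A `qi_spec` object: a tibble with columns `attribute`, `x_min`,
#'   `x_max`, `direction`.
#' @export
build_normalization_spec <- function(records,
                                     attributes = qi_default_attributes(),
                                     directions = qi_default_directions()) {
  check_columns(records, attributes, "quality records")
  defaults <- qi_default_directions()
  rows <- purrr::map(attributes, function(at) {
    x <- records[[at]]
    if (!is.numeric(x) || any(!is.finite(x))) {
      abort(sprintf("attribute `%s` must be finite numeric", at))
    }
    rng <- range(x)
    if (rng[1] == rng[2]) {
      abort(sprintf("attribute `%s` is constant (x_min == x_max); cannot normalize", at))
    }
    dir <- if (at %in% names(directions)) directions[[at]]
           else if (at %in% names(defaults)) defaults[[at]]
           else "higher_is_better"
    if (!dir %in% c("higher_is_better", "lower_is_better")) {
      abort(sprintf("unknown direction `%s` for attribute `%s`", dir, at))
    }
    tibble::tibble(attribute = at, x_min = rng[1], x_max = rng[2], direction = dir)
  })
  structure(dplyr::bind_rows(rows), class = c("qi_spec", "tbl_df", "tbl", "data.frame"))
}

#' Min-max normalize one attribute
#'
#' Applies \eqn{\hat X = (x - x_{min}) / (x_{max} - x_{min})} and reverses it
#' as \eqn{1 - \hat X} for `lower_is_better` attributes, so 1 always means
#' best quality. Values outside the frozen `[x_min, x_max]` range (possible
#' on held-out data) are clipped into `[0, 1]`.
#'
#' @param x Numeric values.
#' @param x_min,x_max Frozen range, `x_max > x_min`.
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @return Numeric values in `[0, 1]`.
#' @export
normalize_attribute <- function(x, x_min, x_max, direction = "higher_is_better") {
  if (x_max <= x_min) abort("x_max must exceed x_min")
  z <- (x - x_min) / (x_max - x_min)
  z <- pmin(pmax(z, 0), 1)
  if (direction == "lower_is_better") 1 - z else z
}

#' Composite quality index
#'
#' Computes the quality index Qi for each record: the equally weighted mean
#' of the normalized attribute values, a dimensionless number in `[0, 1]`
#' where 1 denotes maximum quality. The divisor is the number of attributes
#' averaged per sample (14 under the default attribute set).
#'
#' @param records Quality-record data frame.
#' @param spec A `qi_spec` from [build_normalization_spec()].
#' @param attributes Attributes to average; default: every attribute in the
#'   spec.
#' @param keep_contributions If `TRUE`, keep the per-attribute normalized
#'   columns (prefixed `norm_`) alongside `qi`.
#' @return A tibble: the input records plus a `qi` column, an `n_parameters`
#'   column, and optionally the normalized contributions.
#' @export
compute_qi <- function(records, spec, attributes = spec$attribute,
                       keep_contributions = FALSE) {
  if (!inherits(spec, "qi_spec")) abort("`spec` must be a qi_spec")
  missing_spec <- setdiff(attributes, spec$attribute)
  if (length(missing_spec) > 0) {
    abort(sprintf("attributes missing from spec: %s",
                  paste(missing_spec, collapse = ", ")))
  }
  check_columns(records, attributes, "quality records")
  out <- tibble::as_tibble(records)
  norm <- purrr::map(attributes, function(at) {
    e <- spec[spec$attribute == at, ]
    normalize_attribute(out[[at]], e$x_min, e$x_max, e$direction)
  })
  norm_mat <- do.call(cbind, norm)
  out$qi <- rowMeans(norm_mat)
  out$n_parameters <- length(attributes)
  if (keep_contributions) {
    colnames(norm_mat) <- paste0("norm_", attributes)
    out <- dplyr::bind_cols(out, tibble::as_tibble(norm_mat))
  }
  out
}

#' Serialize / restore a normalization spec
#'
#' A frozen `qi_spec` can be written to JSON so the same attribute ranges and
#' directions are re-applied to new data or audited later.
#'
#' @param spec A `qi_spec`.
#' @param path File path for the JSON spec.
#' @return `write_qi_spec()` returns `path` invisibly; `read_qi_spec()`
#'   returns the restored `qi_spec`.
#' @export
write_qi_spec <- function(spec, path) {
  if (!inherits(spec, "qi_spec")) abort("`spec` must be a qi_spec")
  jsonlite::write_json(as.data.frame(spec), path, digits = NA)
  invisible(path)
}

#' @rdname write_qi_spec
#' @export
read_qi_spec <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(tibble::as_tibble(df), class = c("qi_spec", "tbl_df", "tbl", "data.frame"))
}
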