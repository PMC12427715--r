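#' Run configuration for the storage-study workflow
#'
#' Bundles every tunable of the simulate -> preprocess -> index -> split ->
#' calibrate -> evaluate workflow into one list with validated defaults.
#' `scale = "desk"` uses the reduced factorial ([desk_design()]); `"full"`
#' uses the complete study layout ([study_design()]).
#'
#' @param out_dir Output directory for datasets and reports.
#' @param scale `"desk"` or `"full"`.
#' @param seed Master seed; stage seeds derive from it.
#' @param lo_nm,hi_nm,sg_window,sg_poly_order Preprocessing settings.
#' @param fractions Split fractions (train, test, validation).
#' @param max_components,k_folds PLSR latent-variable search settings.
#' @param mlp An [mlp_config()].
#' @param qi_attributes,qi_directions Quality-index attribute set and
#'   directions.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("dateqi_run_"),
                       scale = c("desk", "full"),
                       seed = 42,
                       lo_nm = 410, hi_nm = 990,
                       sg_window = 13, sg_poly_order = 2,
                       fractions = c(train = 0.7, test = 0.2, validation = 0.1),
                       max_components = 12, k_folds = 10,
                       mlp = mlp_config(seed = seed),
                       qi_attributes = qi_default_attributes(),
                       qi_directions = qi_default_directions()) {
  scale <- match.arg(scale)
  if (abs(sum(fractions) - 1) > 1e-9) abort("split fractions must sum to 1")
  structure(list(
    out_dir = out_dir, scale = scale, seed = as.integer(seed),
    lo_nm = lo_nm, hi_nm = hi_nm,
    sg_window = sg_window, sg_poly_order = sg_poly_order,
    fractions = fractions,
    max_components = max_components, k_folds = k_folds,
    mlp = mlp,
    qi_attributes = qi_attributes, qi_directions = qi_directions
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any subset of the `run_config()` arguments.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mlp_args <- raw$mlp %||% list()
  raw$mlp <- NULL
  cfg <- do.call(run_config, raw)
  cfg$mlp <- do.call(mlp_config, modifyList(list(seed = cfg$seed), mlp_args))
  cfg
}

config_design <- function(config) {
  if (config$scale == "full") study_design(seed = config$seed)
  else desk_design(seed = config$seed)
}

provenance <- function(config) {
  list(
    package_version = as.character(utils::packageVersion("dateqi")),
    seed = config$seed,
    scale = config$scale,
    config_hash = rlang::hash(unclass(config)),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}

#' Simulate a storage study and write its dataset files
#'
#' Generates the synthetic study defined by the configuration and writes the
#' quality, spectra and microbial CSVs plus the regeneration manifest into
#' `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisible named vector of file paths.
#' @export
simulate_study_files <- function(config = run_config()) {
  design <- config_design(config)
  study <- simulate_storage_study(design)
  paths <- write_dataset(study, config$out_dir, design = design)
  invisible(paths)
}

#' Spectra-to-Qi calibration workflow
#'
#' The full modeling pass on one dataset:
#' replicate-aware 70/20/10 split; spectral preprocessing fit on training
#' rows only (window, absorbance, MSC, second derivative); quality-index
#' normalization spec frozen on the training records; per cultivar, a
#' NIPALS PLSR model with grouped-cross-validation latent-variable
#' selection and a feed-forward neural regressor with early stopping on the
#' 20% tuning split; figures of merit with RMSEP, REP and RER computed on
#' the untouched 10% independent split. For the PLSR model the RMSECV
#' column is the grouped k-fold estimate on the training rows; for the
#' neural model it is the replicate-disjoint 20% tuning-split error (a full
#' network re-fit per fold is deliberately avoided).
#'
#' @param records Quality-record tibble.
#' @param spectra Reflectance spectra tibble (`sample_id`,
#'   `replicate_group_id`, metadata, `wl_*` columns).
#' @param config A [run_config()].
#' @return A `calibration_result`: the split, preprocessing pipeline, Qi
#'   spec, per-cultivar `metrics` tibble (model x cultivar rows plus
#'   Combined rows), model objects, and per-cultivar prediction frames.
#' @export
run_calibration_pipeline <- function(records, spectra, config = run_config()) {
  check_columns(spectra, c("sample_id", "replicate_group_id", "cultivar"),
                "spectra table")
  spectra <- set_spectra_mode(tibble::as_tibble(spectra), "reflectance_percent")
  ids <- if ("scan_id" %in% names(spectra)) spectra$scan_id else
    sprintf("row%06d", seq_len(nrow(spectra)))
  spectra$scan_id <- ids

  plan <- split_dataset(
    tibble::tibble(sample_id = ids, replicate_group_id = spectra$replicate_group_id),
    fractions = config$fractions, seed = config$seed)
  subset_of <- setNames(plan$assignments$subset, plan$assignments$sample_id)
  spectra$.subset <- unname(subset_of[ids])

  train_records <- dplyr::filter(
    records, .data$sample_id %in% spectra$sample_id[spectra$.subset == "train"])
  qi_spec <- build_normalization_spec(train_records, config$qi_attributes,
                                      config$qi_directions)
  records_qi <- compute_qi(records, qi_spec)
  qi_of <- setNames(records_qi$qi, records_qi$sample_id)

  pipeline <- fit_spectra_pipeline(
    dplyr::filter(spectra, .data$.subset == "train"),
    lo_nm = config$lo_nm, hi_nm = config$hi_nm,
    sg_window = config$sg_window, sg_poly_order = config$sg_poly_order)
  processed <- apply_spectra_pipeline(pipeline, spectra)
  processed$.qi <- unname(qi_of[processed$sample_id])
  if (any(is.na(processed$.qi))) abort("spectra reference samples without quality records")

  cultivars <- unique(processed$cultivar)
  models <- list()
  predictions <- list()
  metric_rows <- list()
  for (cv_name in cultivars) {
    sub <- dplyr::filter(processed, .data$cultivar == cv_name)
    X <- spectra_matrix(sub)
    y <- sub$.qi
    tr <- sub$.subset == "train"; te <- sub$.subset == "test"
    va <- sub$.subset == "validation"

    cv <- cross_validate_lv(X[tr, , drop = FALSE], y[tr],
                            groups = sub$replicate_group_id[tr],
                            max_components = config$max_components,
                            k_folds = config$k_folds, seed = config$seed)
    plsr <- plsr_fit(X[tr, , drop = FALSE], y[tr], n_components = cv$selected)
    plsr_report <- compute_metrics(
      y_cal = y[tr], yhat_cal = predict(plsr, X[tr, , drop = FALSE]),
      y_cv = y[tr], yhat_cv = cv$predictions_cv,
      y_test = y[va], yhat_test = predict(plsr, X[va, , drop = FALSE]))

    mlp <- mlp_fit(X[tr, , drop = FALSE], y[tr],
                   X[te, , drop = FALSE], y[te], config = config$mlp)
    mlp_report <- compute_metrics(
      y_cal = y[tr], yhat_cal = predict(mlp, X[tr, , drop = FALSE]),
      y_cv = y[te], yhat_cv = predict(mlp, X[te, , drop = FALSE]),
      y_test = y[va], yhat_test = predict(mlp, X[va, , drop = FALSE]))

    models[[cv_name]] <- list(plsr = plsr, mlp = mlp, lv_search = cv)
    predictions[[cv_name]] <- tibble::tibble(
      scan_id = c(sub$scan_id[va], sub$scan_id[va]),
      model = rep(c("PLSR", "ANN"), each = sum(va)),
      observed = c(y[va], y[va]),
      predicted = c(predict(plsr, X[va, , drop = FALSE]),
                    predict(mlp, X[va, , drop = FALSE])))
    metric_rows[[cv_name]] <- dplyr::bind_rows(
      dplyr::mutate(plsr_report, model = "PLSR", cultivar = cv_name, .before = 1),
      dplyr::mutate(mlp_report, model = "ANN", cultivar = cv_name, .before = 1))
  }

  metrics <- dplyr::bind_rows(metric_rows)
  combined <- dplyr::bind_rows(purrr::map(unique(metrics$model), function(m) {
    rows <- dplyr::filter(metrics, .data$model == m)
    if (nrow(rows) < 2) return(NULL)
    dplyr::mutate(aggregate_combined(rows), model = m, .before = 1)
  }))

  structure(list(
    split = plan, qi_spec = qi_spec, pipeline = pipeline,
    metrics = metrics, combined = combined,
    models = models, predictions = dplyr::bind_rows(predictions),
    records_qi = records_qi, config = config
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Spectra-to-Qi calibration\n")
  cols <- c("model", "cultivar", "r_squared", "rmsec", "rmsecv", "rmsep",
            "rep_percent", "rer")
  print(as.data.frame(x$metrics[, cols]), digits = 3, row.names = FALSE)
  if (nrow(x$combined) > 0) {
    cat("Combined rows (per-cultivar means, table precision):\n")
    print(as.data.frame(x$combined), row.names = FALSE)
  }
  invisible(x)
}

#' Degradation-model comparison over a quality dataset
#'
#' Aggregates Qi per (cultivar, month) by the mean, fits linear and
#' quadratic storage-degradation models to each cultivar's series and
#' reports coefficients, fit statistics, AIC and the nested F-test.
#'
#' @param records_qi Quality records carrying a `qi` column (e.g. from
#'   [compute_qi()]), plus `cultivar` and `month`.
#' @param qi_col Name of the Qi column (default `"qi"`; use `"qi_latent"`
#'   to analyze the generator's latent quality).
#' @return A `degradation_report`: per-cultivar comparison objects plus a
#'   tidy `summary` tibble.
#' @export
run_degradation_analysis <- function(records_qi, qi_col = "qi") {
  check_columns(records_qi, c("cultivar", "month", qi_col), "quality records")
  cell_means <- dplyr::summarise(
    dplyr::group_by(records_qi, .data$cultivar, .data$month),
    qi = mean(.data[[qi_col]]), .groups = "drop")
  if (dplyr::n_distinct(cell_means$month) < 4) {
    abort("need at least 4 time points to compare degradation models")
  }
  comparisons <- list()
  rows <- list()
  for (cv_name in unique(cell_means$cultivar)) {
    sub <- dplyr::filter(cell_means, .data$cultivar == cv_name)
    cmp <- compare_degradation_models(sub, t = "month", qi = "qi")
    comparisons[[cv_name]] <- cmp
    rows[[cv_name]] <- tibble::tibble(
      cultivar = cv_name,
      a = cmp$quadratic$a, b = cmp$quadratic$b, c = cmp$quadratic$c,
      r_squared_quadratic = cmp$quadratic$r_squared,
      r_squared_linear = cmp$linear$r_squared,
      aic_linear = cmp$linear$aic, aic_quadratic = cmp$quadratic$aic,
      delta_aic = cmp$delta_aic,
      f_statistic = cmp$f_statistic, p_value = cmp$p_value)
  }
  structure(list(comparisons = comparisons,
                 summary = dplyr::bind_rows(rows),
                 cell_means = cell_means),
            class = "degradation_report")
}

#' @export
print.degradation_report <- function(x, ...) {
  cat("Storage-degradation model comparison (cell-mean Qi per month)\n")
  print(as.data.frame(x$summary), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Orchestrated commands: simulate, analyze, degradation
#'
#' Thin command wrappers matching the workflow stages. `cmd_simulate()`
#' writes the dataset files; `cmd_analyze()` reads them, runs
#' [run_calibration_pipeline()] and writes `metrics.csv` and
#' `analysis_report.json` (figures of merit per model and cultivar, the
#' Combined rows, and a provenance block with the config hash and seeds);
#' `cmd_degradation()` runs [run_degradation_analysis()] on the computed Qi
#' and writes `degradation_report.json`. Each returns its result invisibly.
#'
#' @param config A [run_config()].
#' @return See each command's description.
#' @export
cmd_simulate <- function(config = run_config()) {
  paths <- simulate_study_files(config)
  invisible(paths)
}

#' @rdname cmd_simulate
#' @export
cmd_analyze <- function(config = run_config()) {
  spectra_path <- file.path(config$out_dir, "spectra.csv")
  if (!file.exists(spectra_path)) {
    abort(sprintf("dataset file not found: %s (run cmd_simulate first)", spectra_path))
  }
  data <- read_dataset(config$out_dir)
  result <- run_calibration_pipeline(data$records, data$spectra, config)
  readr::write_csv(result$metrics, file.path(config$out_dir, "metrics.csv"))
  report <- list(
    provenance = provenance(config),
    metrics = as.data.frame(result$metrics),
    combined = as.data.frame(result$combined),
    selected_components = purrr::map(result$models, ~ .x$lv_search$selected)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "analysis_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' @rdname cmd_simulate
#' @export
cmd_degradation <- function(config = run_config()) {
  records_path <- file.path(config$out_dir, "quality_records.csv")
  if (!file.exists(records_path)) {
    abort(sprintf("dataset file not found: %s (run cmd_simulate first)", records_path))
  }
  records <- readr::read_csv(records_path, show_col_types = FALSE)
  spec <- build_normalization_spec(records)
  records_qi <- compute_qi(records, spec)
  report <- run_degradation_analysis(records_qi)
  payload <- list(provenance = provenance(config),
                  summary = as.data.frame(report$summary))
  jsonlite::write_json(payload, file.path(config$out_dir, "degradation_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
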