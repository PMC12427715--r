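#' Moisture-content classification of the study cultivars
#'
#' Per-cultivar, per-group initial moisture content (% dry basis): the mean
#' and standard deviation that define each hydration class of the storage
#' study, for the Sukkary and Khlass cultivars (control plus five
#' progressively rehydrated groups A-E).
#'
#' @return A tibble with columns `cultivar`, `moisture_group`,
#'   `moisture_mean`, `moisture_sd`.
#' @export
moisture_table <- function() {
  tibble::tribble(
    ~cultivar, ~moisture_group, ~moisture_mean, ~moisture_sd,
    "Sukkary", "Control",  4.357, 0.015,
    "Sukkary", "A",       10.531, 0.035,
    "Sukkary", "B",       13.181, 0.011,
    "Sukkary", "C",       16.606, 0.014,
    "Sukkary", "D",       20.489, 0.054,
    "Sukkary", "E",       27.343, 0.016,
    "Khlass",  "Control",  6.235, 0.021,
    "Khlass",  "A",       14.877, 0.023,
    "Khlass",  "B",       21.781, 0.017,
    "Khlass",  "C",       26.807, 0.036,
    "Khlass",  "D",       32.062, 0.046,
    "Khlass",  "E",       38.697, 0.025
  )
}

#' Factorial design of a synthetic storage study
#'
#' Describes the study layout: cultivars, moisture groups, storage
#' temperatures (25, 5, -18 degrees C), packaging types (OCC, CCC, CCSPB,
#' SSPC, PSSPC), monthly time points 0-12, fruits per design cell and
#' instrument scans per fruit. The full design uses 7 fruits per
#' (temperature x packaging) cell, giving 3 x 5 x 7 = 105 fruits per
#' cultivar-group; [desk_design()] is a reduced layout sized for quick runs.
#'
#' @param cultivars,moisture_groups,temperatures,packagings,months Factor
#'   levels of the factorial.
#' @param fruits_per_cell Fruits per (cultivar, group, temperature,
#'   packaging) cell.
#' @param scans_per_fruit Replicate spectra per fruit-month sample.
#' @param seed Integer master seed.
#' @param moisture Moisture classification table (see [moisture_table()]).
#' @return A `study_design` list.
#' @export
study_design <- function(cultivars = c("Sukkary", "Khlass"),
                         moisture_groups = c("Control", "A", "B", "C", "D", "E"),
                         temperatures = c(25, 5, -18),
                         packagings = c("OCC", "CCC", "CCSPB", "SSPC", "PSSPC"),
                         months = 0:12,
                         fruits_per_cell = 7,
                         scans_per_fruit = 3,
                         seed = 42,
                         moisture = moisture_table()) {
  if (fruits_per_cell < 1 || scans_per_fruit < 1) abort("counts must be >= 1")
  if (any(moisture$moisture_sd <= 0)) abort("moisture SDs must be > 0")
  known <- dplyr::filter(moisture, .data$cultivar %in% cultivars,
                         .data$moisture_group %in% moisture_groups)
  if (nrow(known) != length(cultivars) * length(moisture_groups)) {
    abort("moisture table does not cover every (cultivar, moisture_group) pair")
  }
  structure(list(
    cultivars = cultivars, moisture_groups = moisture_groups,
    temperatures = temperatures, packagings = packagings, months = months,
    fruits_per_cell = as.integer(fruits_per_cell),
    scans_per_fruit = as.integer(scans_per_fruit),
    seed = as.integer(seed), moisture = known
  ), class = "study_design")
}

#' @rdname study_design
#' @export
desk_design <- function(seed = 42, fruits_per_cell = 5, scans_per_fruit = 3) {
  study_design(moisture_groups = c("Control", "C", "E"),
               temperatures = c(25, -18),
               packagings = c("OCC", "PSSPC"),
               fruits_per_cell = fruits_per_cell,
               scans_per_fruit = scans_per_fruit,
               seed = seed)
}

#' Degradation-trajectory parameters of the generator
#'
#' Controls how the latent quality and every measured attribute evolve over
#' storage. The cultivar quadratics (`Qi = a t^2 - b t + c`) are the
#' shelf-life models of the two cultivars; the temperature and packaging
#' severity multipliers scale the time-dependent part of every degradation
#' process (warmer storage and poorer barriers degrade faster) and average
#' to 1 over the full design so cell-mean trajectories reproduce the
#' quadratics. Microbial log-CFU trajectories are linear between month-3
#' and month-12 anchors per (cultivar, group, temperature), with additive
#' packaging offsets (zero for the packaging the anchors reference).
#'
#' @param qi_coefficients Per-cultivar quadratic coefficients.
#' @param temperature_severity,packaging_severity Named positive
#'   multipliers.
#' @param qi_noise_sd Per-record noise on the latent quality index.
#' @param microbial_noise_sd Per-record noise on log CFU/g counts.
#' @param sensory_noise_sd Pre-discretization noise on the 1-9 hedonic
#'   scores.
#' @param attribute_noise_sd Relative noise on the physicochemical
#'   attributes.
#' @return A `trajectory_params` list.
#' @export
trajectory_params <- function(
    qi_coefficients = tibble::tribble(
      ~cultivar, ~a, ~b, ~c,
      "Sukkary", -0.0007, 0.0102, 0.9719,
      "Khlass",   0.0021, 0.0521, 0.9554),
    temperature_severity = c(`25` = 1.45, `5` = 1.0, `-18` = 0.55),
    packaging_severity = c(OCC = 1.25, CCC = 1.15, CCSPB = 1.0,
                           SSPC = 0.9, PSSPC = 0.7),
    qi_noise_sd = 0.02,
    microbial_noise_sd = 0.15,
    sensory_noise_sd = 0.5,
    attribute_noise_sd = 0.01) {
  if (any(temperature_severity <= 0) || any(packaging_severity <= 0)) {
    abort("severity multipliers must be > 0")
  }
  if (any(c(qi_noise_sd, microbial_noise_sd, sensory_noise_sd,
            attribute_noise_sd) < 0)) {
    abort("noise scales must be >= 0")
  }
  structure(list(
    qi_coefficients = qi_coefficients,
    temperature_severity = temperature_severity,
    packaging_severity = packaging_severity,
    qi_noise_sd = qi_noise_sd,
    microbial_noise_sd = microbial_noise_sd,
    sensory_noise_sd = sensory_noise_sd,
    attribute_noise_sd = attribute_noise_sd,
    microbial_anchors = microbial_anchor_table(),
    microbial_packaging_offset = c(OCC = 0.8, CCC = 0.6, CCSPB = 0.4,
                                   SSPC = 0.2, PSSPC = 0),
    anchor_reference_packaging = c(Sukkary = "PSSPC", Khlass = "CCC")
  ), class = "trajectory_params")
}

# Month-3 / month-12 log-CFU anchors per (cultivar, group, temperature).
# Sukkary anchors are tabulated directly (PSSPC packaging); Khlass is
# tabulated at 25 C (CCC packaging) and shifted to the other temperatures
# by the Sukkary temperature spacing.
microbial_anchor_table <- function() {
  suk <- tibble::tribble(
    ~moisture_group, ~temperature_C, ~tvc_m3, ~tvc_m12, ~ye_m3, ~ye_m12,
    "Control", -18, 1.1, 1.4, 0.9, 1.2,
    "Control",   5, 2.0, 2.6, 1.8, 2.4,
    "Control",  25, 3.5, 4.3, 3.2, 3.8,
    "A",       -18, 1.6, 2.2, 1.3, 1.9,
    "A",         5, 3.0, 4.0, 2.6, 3.5,
    "A",        25, 4.7, 5.6, 4.2, 5.1,
    "B",       -18, 1.9, 2.6, 1.6, 2.2,
    "B",         5, 3.4, 4.4, 3.1, 4.0,
    "B",        25, 5.2, 6.2, 4.7, 5.6,
    "C",       -18, 2.3, 3.0, 1.9, 2.6,
    "C",         5, 4.2, 5.3, 3.8, 4.8,
    "C",        25, 5.9, 6.9, 5.4, 6.4,
    "D",       -18, 2.7, 3.7, 2.3, 3.1,
    "D",         5, 4.8, 6.0, 4.3, 5.4,
    "D",        25, 6.6, 7.9, 5.9, 7.1,
    "E",       -18, 3.6, 4.5, 3.0, 3.9,
    "E",         5, 5.8, 7.0, 5.3, 6.4,
    "E",        25, 7.6, 8.9, 6.8, 8.1
  )
  suk$cultivar <- "Sukkary"
  khl25 <- tibble::tribble(
    ~moisture_group, ~tvc_m3, ~tvc_m12, ~ye_m3, ~ye_m12,
    "Control", 1.5, 2.5, 1.2, 2.2,
    "A",       2.0, 3.5, 1.8, 3.2,
    "B",       2.5, 4.0, 2.2, 3.7,
    "C",       3.0, 4.5, 2.7, 4.2,
    "D",       3.5, 5.0, 3.2, 4.7,
    "E",       4.0, 5.5, 3.7, 5.2
  )
  suk25 <- dplyr::filter(suk, .data$temperature_C == 25)
  khl <- purrr::map(c(-18, 5, 25), function(temp) {
    shift <- dplyr::left_join(
      dplyr::filter(suk, .data$temperature_C == temp)[, c("moisture_group", "tvc_m3", "tvc_m12", "ye_m3", "ye_m12")],
      suk25[, c("moisture_group", "tvc_m3", "tvc_m12", "ye_m3", "ye_m12")],
      by = "moisture_group", suffix = c("_t", "_25"))
    out <- khl25
    for (col in c("tvc_m3", "tvc_m12", "ye_m3", "ye_m12")) {
      out[[col]] <- pmax(0.05, khl25[[col]] +
                           shift[[paste0(col, "_t")]] - shift[[paste0(col, "_25")]])
    }
    out$temperature_C <- temp
    out
  })
  khl <- dplyr::bind_rows(khl)
  khl$cultivar <- "Khlass"
  dplyr::bind_rows(suk, khl)[, c("cultivar", "moisture_group", "temperature_C",
                                 "tvc_m3", "tvc_m12", "ye_m3", "ye_m12")]
}

#' Generate the fruit roster of a storage study
#'
#' Enumerates the full factorial roster (one row per fruit) with unique
#' fruit IDs, and draws each fruit's initial moisture content from the
#' cultivar/group mean and SD of the moisture classification.
#'
#' @param design A [study_design()].
#' @return A tibble with columns `fruit_id`, `cultivar`, `moisture_group`,
#'   `temperature_C`, `packaging`, `moisture_initial`.
#' @export
generate_design <- function(design = study_design()) {
  if (!inherits(design, "study_design")) abort("`design` must be a study_design")
  roster <- tidyr::expand_grid(
    cultivar = design$cultivars,
    moisture_group = design$moisture_groups,
    temperature_C = design$temperatures,
    packaging = design$packagings,
    fruit = seq_len(design$fruits_per_cell)
  )
  roster$fruit_id <- sprintf("F%06d", seq_len(nrow(roster)))
  roster <- dplyr::left_join(roster, design$moisture,
                             by = c("cultivar", "moisture_group"))
  set.seed(design$seed)
  roster$moisture_initial <- rnorm(nrow(roster), roster$moisture_mean,
                                   roster$moisture_sd)
  roster[, c("fruit_id", "cultivar", "moisture_group", "temperature_C",
             "packaging", "moisture_initial")]
}

#' Generate quality-record trajectories
#'
#' Expands the roster over the monthly time points and simulates every
#' measured attribute. Moisture declines exponentially at a severity-scaled
#' rate; browning index and colour difference grow; pH mildly decreases;
#' hardness drifts upward as the fruit dries (cultivar-specific rate);
#' total soluble solids concentrate as water is lost; water activity tracks
#' moisture. Microbial log counts follow the anchored linear trajectories.
#' The latent quality follows the cultivar quadratic with the
#' time-dependent part scaled by severity, and the seven hedonic scores are
#' a discretized truncated-Gaussian affine map of latent quality onto the
#' 1-9 scale.
#'
#' @param roster Output of [generate_design()].
#' @param params A [trajectory_params()].
#' @param months Time points (months).
#' @param seed Integer seed.
#' @return A quality-record tibble: one row per fruit-month (`sample_id`,
#'   `replicate_group_id`, design columns, physicochemical attributes,
#'   microbial counts, sensory scores, and the generator's latent
#'   `qi_latent`).
#' @export
generate_trajectories <- function(roster, params = trajectory_params(),
                                  months = 0:12, seed = 1) {
  if (!inherits(params, "trajectory_params")) abort("`params` must be trajectory_params")
  check_columns(roster, c("fruit_id", "cultivar", "moisture_group",
                          "temperature_C", "packaging", "moisture_initial"),
                "roster")
  rec <- tidyr::expand_grid(roster, month = months)
  rec$sample_id <- sprintf("%s_m%02d", rec$fruit_id, rec$month)
  rec$replicate_group_id <- rec$sample_id

  sev <- unname(params$temperature_severity[as.character(rec$temperature_C)]) *
    unname(params$packaging_severity[rec$packaging])
  if (any(is.na(sev))) abort("severity multiplier missing for a temperature or packaging level")

  cf <- params$qi_coefficients
  idx <- match(rec$cultivar, cf$cultivar)
  if (any(is.na(idx))) abort("qi_coefficients missing for a cultivar")
  t <- rec$month
  n <- nrow(rec)
  set.seed(seed)

  qi_latent <- cf$c[idx] + (cf$a[idx] * t^2 - cf$b[idx] * t) * sev +
    rnorm(n, 0, params$qi_noise_sd)
  rec$qi_latent <- pmin(pmax(qi_latent, 0), 1)

  rel_noise <- function(base) base * (1 + rnorm(n, 0, params$attribute_noise_sd))
  rec$moisture <- rel_noise(rec$moisture_initial * exp(-0.02 * sev * t))
  rec$aw <- pmin(0.95, pmax(0.05,
    0.30 + 0.012 * rec$moisture + rnorm(n, 0, 0.005)))
  rec$tss <- rel_noise(60 + 0.25 * (rec$moisture_initial - rec$moisture) +
                         0.15 * sev * t)
  rec$bi <- rel_noise(35 + 2.5 * sev * t)
  rec$delta_e <- pmax(0, 0.8 * sev * t + rnorm(n, 0, 0.2))
  rec$ph <- rel_noise(6.1 - 0.02 * sev * t)
  hard_rate <- ifelse(rec$cultivar == "Sukkary", 0.5, 0.8)
  hard_base <- ifelse(rec$cultivar == "Sukkary", 25, 20)
  rec$hardness <- rel_noise(hard_base + hard_rate * sev * t)
  rec$mass <- rel_noise(ifelse(rec$cultivar == "Sukkary", 12, 8) *
                          (1 - 0.004 * sev * t))
  rec$density <- rel_noise(1.2 + 0.002 * sev * t)

  anchors <- dplyr::left_join(
    rec[, c("cultivar", "moisture_group", "temperature_C")],
    params$microbial_anchors,
    by = c("cultivar", "moisture_group", "temperature_C"))
  if (any(is.na(anchors$tvc_m3))) {
    abort("microbial anchors missing for a (cultivar, group, temperature) cell")
  }
  pack_off <- unname(params$microbial_packaging_offset[rec$packaging]) -
    unname(params$microbial_packaging_offset[
      params$anchor_reference_packaging[rec$cultivar]])
  micro_line <- function(m3, m12) {
    slope <- (m12 - m3) / 9
    m3 - 3 * slope + slope * t
  }
  rec$tvc_log <- pmax(0, micro_line(anchors$tvc_m3, anchors$tvc_m12) + pack_off +
                        rnorm(n, 0, params$microbial_noise_sd))
  rec$ye_log <- pmax(0, micro_line(anchors$ye_m3, anchors$ye_m12) + pack_off +
                       rnorm(n, 0, params$microbial_noise_sd))

  sens_cols <- c("sens_texture", "sens_taste", "sens_hardness", "sens_color",
                 "sens_adhesion", "sens_peelability", "sens_overall")
  for (sc in sens_cols) {
    raw <- 1 + 8 * rec$qi_latent + rnorm(n, 0, params$sensory_noise_sd)
    rec[[sc]] <- pmin(9, pmax(1, round(raw)))
  }
  tibble::as_tibble(rec[, c("sample_id", "replicate_group_id", "fruit_id",
                            "cultivar", "moisture_group", "temperature_C",
                            "packaging", "month", "moisture_initial",
                            "moisture", "aw", "tss", "bi", "delta_e", "ph",
                            "hardness", "mass", "density", "tvc_log",
                            "ye_log", sens_cols, "qi_latent")])
}

#' Spectral-generator parameters
#'
#' Defines how reflectance spectra are synthesized from latent attributes:
#' Gaussian absorption bands whose amplitudes are affine-plus-quadratic in
#' a linked attribute (the quadratic term models mild absorbance
#' saturation, a nonlinear attribute-to-spectrum coupling), a linear
#' baseline with a per-scan slope, per-scan multiplicative scatter, and
#' additive reflectance noise. Default bands: visible pigment bands at
#' 450/560/680 nm tied to the browning index, a band near 840 nm tied to
#' total soluble solids, and the water band near 970 nm tied to moisture.
#' These choices are generator conventions, not instrument claims.
#'
#' @param wavelengths Grid in nm (default 411-990 by 3, 194 points).
#' @param bands Tibble: `center`, `width` (nm), `attribute`, `sensitivity`,
#'   `scale` (attribute normalizer).
#' @param nonlinear_gain Quadratic amplitude gain (0 = purely linear
#'   attribute-to-spectrum map).
#' @param baseline_level Baseline absorbance.
#' @param baseline_slope_range Per-scan uniform slope range (absorbance per
#'   normalized wavelength).
#' @param scatter_sd SD of the per-scan log multiplicative scatter factor.
#' @param noise_sd Additive reflectance noise (% reflectance).
#' @return A `spectral_params` list.
#' @export
spectral_params <- function(
    wavelengths = seq(411, 990, by = 3),
    bands = tibble::tribble(
      ~center, ~width, ~attribute, ~sensitivity, ~scale,
      450, 40, "bi",        0.35, 100,
      560, 50, "bi",        0.25, 100,
      680, 40, "bi",        0.20, 100,
      840, 35, "tss",       0.30, 100,
      970, 30, "moisture",  0.50, 40),
    nonlinear_gain = 0.5,
    baseline_level = 0.3,
    baseline_slope_range = c(-0.05, 0.05),
    scatter_sd = 0.05,
    noise_sd = 0.15) {
  check_uniform_grid(wavelengths)
  if (any(bands$width <= 0)) abort("band widths must be > 0")
  if (any(bands$center < min(wavelengths) | bands$center > max(wavelengths))) {
    abort("band centers must lie inside the wavelength grid")
  }
  structure(list(
    wavelengths = wavelengths, bands = bands,
    nonlinear_gain = nonlinear_gain,
    baseline_level = baseline_level,
    baseline_slope_range = baseline_slope_range,
    scatter_sd = scatter_sd, noise_sd = noise_sd
  ), class = "spectral_params")
}

#' Generate replicate reflectance spectra for quality records
#'
#' Builds each scan in absorbance space (baseline plus attribute-linked
#' Gaussian bands), converts to percent reflectance
#' (\eqn{R\% = 100 \cdot 10^{-A}}), applies a per-scan multiplicative
#' scatter factor and additive noise. `scans_per_fruit` scans share one
#' `replicate_group_id`, emulating repeated instrument scans of one sample.
#'
#' @param records Quality-record tibble from [generate_trajectories()].
#' @param params A [spectral_params()].
#' @param scans_per_fruit Replicate scans per record.
#' @param seed Integer seed.
#' @return A wide spectra tibble in `reflectance_percent` mode.
#' @export
generate_spectra <- function(records, params = spectral_params(),
                             scans_per_fruit = 3, seed = 1) {
  if (!inherits(params, "spectral_params")) abort("`params` must be spectral_params")
  needed <- unique(params$bands$attribute)
  check_columns(records, c("sample_id", "replicate_group_id", needed),
                "quality records")
  wl <- params$wavelengths
  p <- length(wl)
  n_rec <- nrow(records)

  # per-record band amplitudes: sensitivity * (x + gain * x^2), x normalized
  amp <- matrix(0, n_rec, nrow(params$bands))
  shapes <- matrix(0, nrow(params$bands), p)
  for (b in seq_len(nrow(params$bands))) {
    bb <- params$bands[b, ]
    x <- records[[bb$attribute]] / bb$scale
    amp[, b] <- bb$sensitivity * (x + params$nonlinear_gain * x^2)
    shapes[b, ] <- exp(-0.5 * ((wl - bb$center) / bb$width)^2)
  }
  A_signal <- amp %*% shapes

  set.seed(seed)
  n_scan <- n_rec * scans_per_fruit
  rec_idx <- rep(seq_len(n_rec), each = scans_per_fruit)
  slope <- runif(n_scan, params$baseline_slope_range[1],
                 params$baseline_slope_range[2])
  wl_norm <- (wl - mean(wl)) / diff(range(wl))
  A <- A_signal[rec_idx, , drop = FALSE] +
    params$baseline_level + outer(slope, wl_norm)
  scatter <- exp(rnorm(n_scan, 0, params$scatter_sd))
  R <- 100 * 10^(-A) * scatter +
    matrix(rnorm(n_scan * p, 0, params$noise_sd), n_scan, p)
  R <- pmax(R, 0.01)
  colnames(R) <- wl_names(wl)

  meta_cols <- intersect(c("sample_id", "replicate_group_id", "fruit_id",
                           "cultivar", "moisture_group", "temperature_C",
                           "packaging", "month"), names(records))
  out <- dplyr::bind_cols(
    tibble::as_tibble(records[rec_idx, meta_cols, drop = FALSE]),
    tibble::tibble(scan = rep(seq_len(scans_per_fruit), times = n_rec)),
    tibble::as_tibble(R)
  )
  out$scan_id <- sprintf("%s_s%d", out$sample_id, out$scan)
  out <- dplyr::relocate(out, "scan_id", .before = 1)
  set_spectra_mode(out, "reflectance_percent")
}

#' Simulate a complete storage study
#'
#' Convenience wrapper: roster, quality records and replicate spectra in
#' one call, fully determined by the design seed (stage seeds are derived
#' from it).
#'
#' @param design A [study_design()].
#' @param trajectories A [trajectory_params()].
#' @param spectra A [spectral_params()].
#' @return A list with `roster`, `records` and `spectra`.
#' @export
simulate_storage_study <- function(design = desk_design(),
                                   trajectories = trajectory_params(),
                                   spectra = spectral_params()) {
  roster <- generate_design(design)
  records <- generate_trajectories(roster, trajectories,
                                   months = design$months,
                                   seed = design$seed + 1L)
  spec <- generate_spectra(records, spectra,
                           scans_per_fruit = design$scans_per_fruit,
                           seed = design$seed + 2L)
  list(roster = roster, records = records, spectra = spec)
}

#' Write / read a synthetic dataset
#'
#' Emits the quality-record CSV, the wide spectra CSV, a microbial CSV
#' (`sample_id`, `tvc_log`, `ye_log`) and a manifest JSON capturing the
#' seed and design so the dataset can be regenerated bit-identically.
#'
#' @param study Output of [simulate_storage_study()].
#' @param dir Output directory (created if needed).
#' @param design The design used (stored in the manifest).
#' @return `write_dataset()`: invisible named vector of file paths.
#'   `read_dataset()`: list with `records`, `spectra`, `microbial`,
#'   `manifest`.
#' @export
write_dataset <- function(study, dir, design = NULL) {
  if (!all(study$spectra$sample_id %in% study$records$sample_id)) {
    abort("spectra reference sample_ids absent from the quality records")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(records = file.path(dir, "quality_records.csv"),
             spectra = file.path(dir, "spectra.csv"),
             microbial = file.path(dir, "microbial.csv"),
             manifest = file.path(dir, "manifest.json"))
  readr::write_csv(study$records, paths[["records"]])
  readr::write_csv(study$spectra, paths[["spectra"]])
  readr::write_csv(study$records[, c("sample_id", "tvc_log", "ye_log")],
                   paths[["microbial"]])
  manifest <- list(
    n_records = nrow(study$records),
    n_spectra = nrow(study$spectra)
  )
  if (!is.null(design)) {
    d <- unclass(design)
    d$moisture <- NULL
    manifest$design <- d
    manifest$seed <- design$seed
  }
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  records <- readr::read_csv(file.path(dir, "quality_records.csv"),
                             show_col_types = FALSE)
  spectra <- readr::read_csv(file.path(dir, "spectra.csv"),
                             show_col_types = FALSE)
  spectra <- set_spectra_mode(spectra, "reflectance_percent")
  list(
    records = records,
    spectra = spectra,
    microbial = readr::read_csv(file.path(dir, "microbial.csv"),
                                show_col_types = FALSE),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)
  )
}
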