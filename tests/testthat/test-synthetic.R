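test_that("the factorial roster has the advertised arithmetic", {
  roster <- generate_design(study_design())
  # 2 cultivars x 6 groups x 3 temperatures x 5 packagings x 7 fruits
  expect_equal(nrow(roster), 2 * 6 * 3 * 5 * 7)
  expect_false(anyDuplicated(roster$fruit_id) > 0)
  per_cg <- dplyr::count(roster, cultivar, moisture_group)
  expect_true(all(per_cg$n == 105))   # 3 x 5 x 7 fruits per cultivar-group

  desk <- simulate_storage_study(desk_design())
  expect_equal(nrow(desk$roster), 2 * 3 * 2 * 2 * 5)
  expect_equal(nrow(desk$records), nrow(desk$roster) * 13)
  expect_equal(nrow(desk$spectra), nrow(desk$records) * 3)
  expect_false(anyDuplicated(desk$records$sample_id) > 0)
  expect_false(anyDuplicated(desk$spectra$scan_id) > 0)
  # every scan's replicate group is its sample
  expect_true(all(desk$spectra$replicate_group_id == desk$spectra$sample_id))
})

test_that("generation is deterministic in the design seed", {
  d <- desk_design(seed = 7, fruits_per_cell = 2)
  s1 <- simulate_storage_study(d)
  s2 <- simulate_storage_study(d)
  expect_identical(s1, s2)
  s3 <- simulate_storage_study(desk_design(seed = 8, fruits_per_cell = 2))
  expect_false(identical(s1$records$qi_latent, s3$records$qi_latent))
})

test_that("initial moisture draws reproduce the classification table", {
  design <- study_design(cultivars = "Sukkary", moisture_groups = "A",
                         temperatures = 25, packagings = "OCC",
                         fruits_per_cell = 10000, scans_per_fruit = 1,
                         seed = 3)
  roster <- generate_design(design)
  expect_equal(mean(roster$moisture_initial), 10.531, tolerance = 0.05 / 10.531)
  expect_equal(sd(roster$moisture_initial), 0.035, tolerance = 0.05)
})

test_that("severity multipliers average to one over the full design", {
  p <- trajectory_params()
  expect_equal(mean(p$temperature_severity), 1)
  expect_equal(mean(p$packaging_severity), 1)
})

test_that("microbial trajectories hit the tabulated endpoint for the worst cell", {
  design <- study_design(cultivars = "Sukkary", moisture_groups = "E",
                         temperatures = 25, packagings = "PSSPC",
                         fruits_per_cell = 300, scans_per_fruit = 1,
                         months = c(3, 12), seed = 11)
  rec <- generate_trajectories(generate_design(design), months = design$months,
                               seed = design$seed + 1L)
  m12 <- rec[rec$month == 12, ]
  m3 <- rec[rec$month == 3, ]
  expect_equal(mean(m12$tvc_log), 8.9, tolerance = 0.3 / 8.9)
  expect_equal(mean(m3$tvc_log), 7.6, tolerance = 0.3 / 7.6)
  expect_equal(mean(m12$ye_log), 8.1, tolerance = 0.3 / 8.1)
  # a release screen on this cell must exclude the batch
  expect_equal(screen_batch(m12)$batch_status, "excluded")
})

test_that("with noise switched off the latent quality is the scaled quadratic", {
  params <- trajectory_params(qi_noise_sd = 0, microbial_noise_sd = 0,
                              sensory_noise_sd = 0, attribute_noise_sd = 0)
  design <- study_design(cultivars = "Sukkary", moisture_groups = "Control",
                         temperatures = 25, packagings = "OCC",
                         fruits_per_cell = 1, scans_per_fruit = 1, seed = 1)
  rec <- generate_trajectories(generate_design(design), params,
                               months = 0:12, seed = 2)
  sev <- 1.45 * 1.25
  t <- 0:12
  expected <- pmin(pmax(0.9719 + (-0.0007 * t^2 - 0.0102 * t) * sev, 0), 1)
  expect_equal(rec$qi_latent, expected, tolerance = 1e-12)
  # deterministic attribute trajectories
  expect_equal(rec$bi, 35 + 2.5 * sev * t, tolerance = 1e-12)
  expect_equal(rec$ph, 6.1 - 0.02 * sev * t, tolerance = 1e-12)
  expect_equal(rec$moisture, rec$moisture_initial * exp(-0.02 * sev * t),
               tolerance = 1e-12)
  # sensory scores are the discretized affine map of latent quality
  expect_equal(rec$sens_overall, pmin(9, pmax(1, round(1 + 8 * rec$qi_latent))))
  expect_true(all(rec$sens_taste >= 1 & rec$sens_taste <= 9))
})

test_that("harsher storage degrades faster at every time point", {
  params <- trajectory_params(qi_noise_sd = 0, microbial_noise_sd = 0,
                              sensory_noise_sd = 0, attribute_noise_sd = 0)
  design <- study_design(moisture_groups = "C",
                         temperatures = c(25, -18),
                         packagings = c("OCC", "PSSPC"),
                         fruits_per_cell = 1, scans_per_fruit = 1, seed = 4)
  rec <- generate_trajectories(generate_design(design), params,
                               months = c(6, 12), seed = 5)
  by_cell <- dplyr::summarise(
    dplyr::group_by(rec, cultivar, month),
    harsh = qi_latent[temperature_C == 25 & packaging == "OCC"],
    mild = qi_latent[temperature_C == -18 & packaging == "PSSPC"],
    .groups = "drop")
  expect_true(all(by_cell$harsh < by_cell$mild))
})

test_that("the water band couples monotonically to moisture", {
  rec <- tibble::tibble(
    sample_id = sprintf("s%d", 1:5),
    replicate_group_id = sprintf("s%d", 1:5),
    bi = 35, tss = 60,
    moisture = c(5, 10, 20, 30, 40))
  quiet <- spectral_params(noise_sd = 0, scatter_sd = 0,
                           baseline_slope_range = c(0, 0))
  sp <- generate_spectra(rec, quiet, scans_per_fruit = 1, seed = 1)
  r970 <- sp$wl_0969
  expect_true(all(diff(r970) < 0))   # more water -> more absorption -> less R
  # far from every band the signal is just the baseline
  expect_equal(sp$wl_0411, rep(100 * 10^(-(0.3 + 0.35 * 0.35 *
    (1 + 0.5 * 0.35) * exp(-0.5 * ((411 - 450) / 40)^2) -
    0)), 5), tolerance = 0.5)
})

test_that("generator input validation catches incomplete specifications", {
  expect_error(study_design(moisture_groups = "Z"), "cover")
  expect_error(study_design(fruits_per_cell = 0), ">= 1")
  expect_error(trajectory_params(qi_noise_sd = -1), ">= 0")
  expect_error(spectral_params(bands = tibble::tibble(
    center = 2000, width = 10, attribute = "bi", sensitivity = 1, scale = 1)),
    "inside")
  roster <- generate_design(desk_design(fruits_per_cell = 1))
  expect_error(generate_trajectories(roster[, -1]), "fruit_id")
})

test_that("datasets round-trip through CSV plus manifest", {
  design <- desk_design(seed = 12, fruits_per_cell = 1, scans_per_fruit = 2)
  study <- simulate_storage_study(design)
  dir <- withr::local_tempdir()
  paths <- write_dataset(study, dir, design = design)
  expect_true(all(file.exists(paths)))
  back <- read_dataset(dir)
  expect_equal(as.data.frame(back$records), as.data.frame(study$records),
               tolerance = 1e-12)
  expect_equal(spectra_matrix(back$spectra), spectra_matrix(study$spectra),
               tolerance = 1e-12)
  expect_equal(spectra_mode(back$spectra), "reflectance_percent")
  expect_equal(back$manifest$seed, 12)
  expect_equal(back$manifest$n_records, nrow(study$records))
  expect_equal(back$microbial$tvc_log, study$records$tvc_log, tolerance = 1e-12)
})
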