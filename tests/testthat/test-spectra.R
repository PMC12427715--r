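test_that("windowing retains exactly the in-range grid points", {
  full_grid <- seq(285, 1200, 3)
  s <- make_spectra(matrix(50, 2, length(full_grid)), wavelengths = full_grid)
  w <- window_spectra(s, 410, 990)
  wl <- spectra_wavelengths(w)
  expect_length(wl, 194)
  expect_equal(range(wl), c(411, 990))

  inside <- make_spectra(matrix(50, 1, 194))
  expect_equal(spectra_wavelengths(window_spectra(inside)), seq(411, 990, 3))
  expect_error(window_spectra(inside, 2000, 2100), "no grid points")
})

test_that("reflectance converts to absorbance on the decade scale", {
  s <- make_spectra(matrix(c(100, 10, 1), 1, 3), wavelengths = c(500, 503, 506))
  a <- reflectance_to_absorbance(s)
  expect_equal(unname(unlist(a[, wl <- c("wl_0500", "wl_0503", "wl_0506")])),
               c(0, 1, 2))
  expect_equal(spectra_mode(a), "absorbance")
  bad <- make_spectra(matrix(c(50, -1, 10), 1, 3), wavelengths = c(500, 503, 506))
  expect_error(reflectance_to_absorbance(bad), "> 0")
  expect_error(reflectance_to_absorbance(a), "reflectance_percent")
})

test_that("MSC inverts affine scatter against the reference", {
  set.seed(5)
  wl <- seq(411, 990, 3)
  base <- 0.5 + 0.3 * exp(-0.5 * ((wl - 700) / 60)^2)
  rows <- rbind(base, 2 * base + 3, 0.5 * base - 0.1)
  s <- make_spectra(rows, mode = "absorbance")
  corrected <- msc_correct(s, reference = base)
  m <- spectra_matrix(corrected)
  for (i in 1:3) expect_equal(unname(m[i, ]), unname(base), tolerance = 1e-10)

  # default reference = column mean; post-correction regression on the
  # reference has slope 1 and intercept 0
  noisy <- base + matrix(rnorm(5 * length(wl), 0, 0.01), 5, byrow = TRUE)
  noisy <- noisy * runif(5, 0.7, 1.4) + runif(5, -0.2, 0.2)
  sn <- make_spectra(noisy, mode = "absorbance")
  cn <- msc_correct(sn)
  ref <- attr(cn, "msc_reference")
  mm <- spectra_matrix(cn)
  for (i in 1:5) {
    cf <- coef(lm(mm[i, ] ~ ref))
    expect_equal(unname(cf), c(0, 1), tolerance = 1e-10)
  }
  expect_error(msc_correct(make_spectra(base, mode = "absorbance")), ">= 2")
})

test_that("SG second derivative is exact on polynomials and accurate on sine", {
  wl <- seq(411, 990, 3)
  quad <- make_spectra(rbind(wl^2, 5 * wl + 2), mode = "absorbance")
  d2 <- savitzky_golay_d2(quad, window_points = 13)
  m <- spectra_matrix(d2)
  expect_equal(unname(m[1, ]), rep(2, ncol(m)), tolerance = 1e-10)
  expect_equal(unname(m[2, ]), rep(0, ncol(m)), tolerance = 1e-10)
  # trimmed to the valid interior: 6 points lost per edge at window 13
  expect_length(spectra_wavelengths(d2), length(wl) - 12)

  # analytic oracle on a unit-spaced grid, where an 11-point window spans
  # a small fraction of the sine period
  wl_unit <- 411:990
  sine <- make_spectra(sin(wl_unit / 20), wavelengths = wl_unit,
                       mode = "absorbance")
  d2s <- savitzky_golay_d2(sine, window_points = 11)
  wl_out <- spectra_wavelengths(d2s)
  expect_lt(max(abs(spectra_matrix(d2s)[1, ] - (-(1 / 400) * sin(wl_out / 20)))),
            1e-4)

  expect_error(savitzky_golay_d2(sine, window_points = 12), "odd")
  expect_error(savitzky_golay_d2(sine, window_points = 3), ">= 5")
})

test_that("SG derivative matches the signal-package filter on interior points", {
  skip_if_not_installed("signal")
  wl <- seq(411, 990, 3)
  set.seed(9)
  y <- 0.5 + 0.2 * sin(wl / 40) + rnorm(length(wl), 0, 0.01)
  ours <- spectra_matrix(savitzky_golay_d2(make_spectra(y, mode = "absorbance"),
                                           window_points = 11))[1, ]
  theirs <- signal::sgolayfilt(y, p = 2, n = 11, m = 2, ts = 3)
  interior <- 6:(length(wl) - 5)
  expect_equal(unname(ours), unname(theirs[interior]), tolerance = 1e-10)
})

test_that("SG-d2 is linear and windowing commutes with absorbance conversion", {
  wl <- seq(411, 990, 3)
  set.seed(2)
  x <- runif(length(wl), 0.2, 0.8)
  y <- runif(length(wl), 0.2, 0.8)
  d2 <- function(v) spectra_matrix(
    savitzky_golay_d2(make_spectra(v, mode = "absorbance")))[1, ]
  expect_equal(d2(2 * x + 3 * y), 2 * d2(x) + 3 * d2(y), tolerance = 1e-10)

  r <- make_spectra(matrix(runif(2 * length(wl), 20, 90), 2),
                    wavelengths = wl)
  path1 <- reflectance_to_absorbance(window_spectra(r, 500, 800))
  path2 <- window_spectra(reflectance_to_absorbance(r), 500, 800)
  expect_equal(spectra_matrix(path1), spectra_matrix(path2))
})

test_that("the fitted pipeline is deterministic and leakage-free on new data", {
  design <- study_design(moisture_groups = c("Control", "E"),
                         temperatures = 25, packagings = "PSSPC",
                         fruits_per_cell = 3, months = c(0, 6, 12), seed = 10)
  study <- simulate_storage_study(design)
  sp <- study$spectra
  train <- sp[1:40, ]
  pipeline <- fit_spectra_pipeline(train)
  out1 <- apply_spectra_pipeline(pipeline, sp)
  out2 <- apply_spectra_pipeline(pipeline, sp)
  expect_identical(out1, out2)
  expect_equal(spectra_mode(out1), "d2_absorbance")
  # row order preserved
  expect_equal(out1$scan_id, sp$scan_id)
  # two identical input rows give identical preprocessed rows
  dup <- sp[c(1, 1), ]
  dup$scan_id <- c("a", "b")
  odup <- apply_spectra_pipeline(pipeline, dup)
  expect_equal(unname(spectra_matrix(odup)[1, ]), unname(spectra_matrix(odup)[2, ]))
  # pipeline state depends only on training rows
  pipeline2 <- fit_spectra_pipeline(train)
  expect_identical(pipeline, pipeline2)
})

test_that("MSC reduces between-replicate scatter variance on synthetic spectra", {
  design <- study_design(moisture_groups = "C", temperatures = 5,
                         packagings = "CCC", fruits_per_cell = 6,
                         months = 0, seed = 77, scans_per_fruit = 4)
  study <- simulate_storage_study(design)
  absorb <- reflectance_to_absorbance(window_spectra(study$spectra))
  before <- spectra_matrix(absorb)
  after <- spectra_matrix(msc_correct(absorb))
  within_var <- function(m) {
    mean(tapply(seq_len(nrow(m)), study$spectra$replicate_group_id, function(i) {
      mean(apply(m[i, , drop = FALSE], 2, var))
    }))
  }
  expect_lt(within_var(after), within_var(before))
})
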