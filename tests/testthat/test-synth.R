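test_that("rendered apples are deterministic and match their drawn geometry", {
  spec <- image_spec(diameter_px = 100, aspect = 1, defect_fraction = 0.02,
                     seed = 11)
  a <- render_apple(spec)
  b <- render_apple(spec)
  expect_identical(a$image, b$image)                  # byte-identical render

  m <- measure_apple(a$image)
  expect_lt(abs(m$wp - 100), 2)
  expect_lt(abs(m$lambda - 1), 0.02)

  clean <- render_apple(image_spec(diameter_px = 120, defect_fraction = 0, seed = 3))
  expect_equal(clean$truth$t, 0)
  expect_equal(measure_apple(clean$image)$t, 0)       # nothing dark to find
})

test_that("ground truth satisfies the appearance invariants", {
  set.seed(77)
  for (i in 1:6) {
    spec <- image_spec(diameter_px = runif(1, 90, 180),
                       aspect = runif(1, 0.9, 1.15),
                       defect_fraction = runif(1, 0, 0.05),
                       n_defect_blobs = sample(1:4, 1), seed = i)
    tr <- render_apple(spec)$truth
    expect_true(tr$t >= 0 && tr$t <= 1)
    expect_gt(tr$lambda, 0)
    expect_gte(tr$wp, 0)
    expect_equal(tr$defect_label, classify_defect(tr$t))
    expect_equal(tr$shape_label, classify_shape(tr$lambda))
    expect_equal(tr$size_label, classify_size(tr$wp))
  }
})

test_that("oversized fruit and invalid specs are rejected", {
  expect_error(render_apple(image_spec(diameter_px = 300, frame = 256)),
               class = "fujigrade_render_error")
  expect_error(image_spec(diameter_px = 10), class = "fujigrade_invalid_parameter")
  expect_error(image_spec(defect_fraction = 0.5), class = "fujigrade_invalid_parameter")
  expect_error(image_spec(aspect = 0), class = "fujigrade_invalid_parameter")
})

test_that("calibration pairs follow the generating line", {
  exact <- make_calibration_pairs(25, noise_sd = 0, seed = 8)
  cal <- fit_size_calibration(exact)
  expect_equal(cal$slope, 0.4052, tolerance = 1e-10)
  expect_equal(cal$intercept, 13.5015, tolerance = 1e-8)

  expect_identical(make_calibration_pairs(30, seed = 4),
                   make_calibration_pairs(30, seed = 4))
  expect_error(make_calibration_pairs(1), class = "fujigrade_invalid_parameter")
})

test_that("noise-free spectra lie exactly in the affine span of the generator basis", {
  sim <- simulate_spectra(spectra_spec(n_samples = 10, n_wavelengths = 150,
                                       scatter_on = FALSE, noise_sd = 0,
                                       seed = 13))
  basis <- attr(sim$spectra, "basis")
  fit <- lm.fit(cbind(1, basis), t(sim$spectra$reflectance))
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("the Brix distribution matches the specified truncated normal", {
  sim <- simulate_spectra(spectra_spec(n_samples = 10000, n_wavelengths = 12,
                                       n_clutter = 0, seed = 17))
  brix <- sim$spectra$brix
  expect_true(all(brix >= 8.9 & brix <= 14.6))
  expect_lt(abs(mean(brix) - 11.7) / 11.7, 0.02)
  expect_lt(abs(sd(brix) - 1.06) / 1.06, 0.05)  # SD of the truncated normal

  again <- simulate_spectra(spectra_spec(n_samples = 10000, n_wavelengths = 12,
                                         n_clutter = 0, seed = 17))
  expect_identical(sim$spectra$reflectance, again$spectra$reflectance)
})

test_that("reflectance correction recovers generated reflectance exactly", {
  sim <- simulate_spectra(spectra_spec(n_samples = 4, n_wavelengths = 40,
                                       scatter_on = FALSE, noise_sd = 0,
                                       seed = 19))
  truth <- sim$spectra$reflectance[1, ]
  iw <- rep(4000, 40); id <- rep(150, 40)
  raw <- tibble::tibble(wavelength_nm = sim$spectra$wavelengths,
                        intensity = id + truth * (iw - id),
                        white_reference = iw, dark_reference = id)
  expect_equal(reflectance_correct(raw)$reflectance, unname(truth),
               tolerance = 1e-12)
})
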