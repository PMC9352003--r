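test_that("black/white correction maps counts to reflectance", {
  wl <- 1:5
  mk <- function(i) tibble::tibble(wavelength_nm = wl, intensity = i,
                                   white_reference = 200, dark_reference = 40)
  expect_equal(reflectance_correct(mk(200))$reflectance, rep(1, 5))
  expect_equal(reflectance_correct(mk(40))$reflectance, rep(0, 5))
  expect_equal(reflectance_correct(mk(120))$reflectance, rep(0.5, 5))

  bad <- tibble::tibble(wavelength_nm = 1, intensity = 1,
                        white_reference = 7, dark_reference = 7)
  expect_error(reflectance_correct(bad), class = "fujigrade_degenerate_reference")
})

test_that("wavelength decimation keeps one point in every stride", {
  ss <- spectra_set(seq(400, 1000, length.out = 1771),
                    matrix(runif(2 * 1771), nrow = 2))
  expect_length(downsample_wavelengths(ss, 3)$wavelengths, 591)

  s10 <- spectra_set(1:10, matrix(1:10, nrow = 1))
  expect_equal(downsample_wavelengths(s10, 3)$wavelengths, c(1, 4, 7, 10))
  expect_equal(downsample_wavelengths(s10, 1)$wavelengths, 1:10)
  expect_error(downsample_wavelengths(s10, 0), class = "fujigrade_invalid_parameter")
})

test_that("MSC inverts affine scatter against the reference", {
  ss <- toy_spectra(n = 6, w = 50, noise = 0)
  ref <- colMeans(ss$reflectance)

  distorted <- ss
  distorted$reflectance[1, ] <- 2 * ref + 0.3
  out <- msc(distorted, reference = ref)
  expect_equal(unname(out$reflectance[1, ]), unname(ref), tolerance = 1e-10)

  same <- spectra_set(ss$wavelengths, rbind(ref, ref + 0.001))
  expect_equal(unname(msc(same, reference = ref)$reflectance[1, ]), unname(ref),
               tolerance = 1e-10)

  flat <- spectra_set(1:5, matrix(runif(10), 2))
  expect_error(msc(flat, reference = rep(1, 5)),
               class = "fujigrade_degenerate_reference")
})

test_that("MSC shrinks scatter-induced spread at least five-fold", {
  set.seed(31)
  ss <- toy_spectra(n = 20, w = 60, noise = 0)
  clean <- ss$reflectance
  b <- runif(20, 0.7, 1.3); a <- runif(20, -0.1, 0.1)
  scattered <- spectra_set(ss$wavelengths, clean * b + a, brix = ss$brix)

  spread <- function(R) mean(apply(R, 2, sd))
  corrected <- msc(scattered)
  expect_gt(spread(scattered$reflectance) / spread(corrected$reflectance), 5)
  # shape preserved
  expect_equal(dim(corrected$reflectance), dim(clean))
})

test_that("SNV standardizes each spectrum and is affine invariant", {
  ss <- toy_spectra(n = 8, w = 40)
  out <- snv(ss)
  expect_equal(unname(rowMeans(out$reflectance)), rep(0, 8), tolerance = 1e-10)
  expect_equal(unname(apply(out$reflectance, 1, sd)), rep(1, 8), tolerance = 1e-10)

  # idempotent, and invariant to per-spectrum affine rescaling (a > 0)
  expect_equal(snv(out)$reflectance, out$reflectance, tolerance = 1e-10)
  rescaled <- spectra_set(ss$wavelengths, ss$reflectance * 3.7 - 0.42)
  expect_equal(unname(snv(rescaled)$reflectance), unname(out$reflectance),
               tolerance = 1e-10)

  flat <- spectra_set(1:4, matrix(c(1, 1, 1, 1), nrow = 1))
  expect_error(snv(flat), class = "fujigrade_degenerate_spectrum")
})

test_that("Brix grading thresholds at 13 and 10 °Brix", {
  expect_equal(classify_brix(c(13, 10, 0, 14.6, 9.99)),
               c("high", "medium", "low", "high", "low"))
  expect_error(classify_brix(-1), class = "fujigrade_invalid_parameter")
})
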