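#' Specification of synthetic NIR apple spectra
#'
#' Parameters for [simulate_spectra()]. Each clean spectrum is a smooth
#' reflectance baseline minus Gaussian absorption bands whose depths are
#' proportional to the sample's Brix value (the planted signal), minus
#' pigment interference bands with random Brix-independent amplitudes;
#' the observed spectrum is a per-sample affine scatter distortion
#' (`b_i * clean + a_i`) plus white noise. Defaults emulate a 168-sample
#' Red Fuji campaign: Brix drawn from a Normal(11.7, 1.1) truncated to
#' [8.9, 14.6] °Brix, 1771 wavelengths over 400-1000 nm.
#'
#' @param n_samples Number of samples (`>= 4`).
#' @param n_wavelengths Grid size over `wl_range` (default 1771).
#' @param wl_range Wavelength range, nm.
#' @param brix_mean,brix_sd,brix_range Truncated-normal Brix
#'   distribution, °Brix.
#' @param band_centers,band_widths,band_gains Brix-linked absorption
#'   bands: centres (nm), Gaussian widths (nm), and depth per °Brix
#'   (reflectance units).
#' @param band_noise_sd Per-sample, per-band amplitude noise in °Brix
#'   equivalents: band b of sample i has depth
#'   `band_gains[b] * (brix_i + N(0, band_noise_sd))`, so the bands are
#'   informative but not perfectly redundant (matrix and temperature
#'   effects perturb each band independently).
#' @param interferent_centers,interferent_widths,interferent_sd
#'   Brix-independent pigment bands with amplitudes drawn per sample
#'   from `|N(0, interferent_sd)|`.
#' @param n_clutter,clutter_sd,clutter_wl_range,clutter_width_range
#'   Broad-band spectral clutter: `n_clutter` Gaussian components with
#'   centres drawn over `clutter_wl_range` and widths over
#'   `clutter_width_range` (nm), each with an independent per-sample
#'   amplitude `N(0, clutter_sd)`. Emulates pigment, water-content and
#'   tissue-structure variability unrelated to sugar content.
#' @param scatter_on Apply per-sample multiplicative/additive scatter?
#' @param scatter_slope_range,scatter_offset_range Uniform ranges for
#'   the scatter coefficients `b_i` and `a_i`.
#' @param noise_sd White-noise SD in reflectance units, in the quiet
#'   analytical window of the detector.
#' @param noise_window Wavelength interval (nm) of the low-noise
#'   analytical window; outside it the noise SD is multiplied by
#'   `noise_edge_factor` (detector sensitivity falls off toward the
#'   edges of the spectral range, so those channels are far noisier).
#' @param noise_edge_factor Multiplier on `noise_sd` outside
#'   `noise_window` (`>= 1`).
#' @param seed Integer seed.
#' @return An object of class `spectra_spec`.
#' @export
spectra_spec <- function(n_samples = 168, n_wavelengths = 1771,
                         wl_range = c(400, 1000),
                         brix_mean = 11.7, brix_sd = 1.1,
                         brix_range = c(8.9, 14.6),
                         band_centers = c(745, 842, 912, 962),
                         band_widths = c(2.5, 2.5, 2.5, 2.5),
                         band_gains = c(0.008, 0.010, 0.012, 0.010),
                         band_noise_sd = 0,
                         interferent_centers = c(550, 680),
                         interferent_widths = c(28, 16),
                         interferent_sd = 0.04,
                         n_clutter = 24, clutter_sd = 0.02,
                         clutter_wl_range = c(420, 700),
                         clutter_width_range = c(15, 60),
                         scatter_on = TRUE,
                         scatter_slope_range = c(0.7, 1.3),
                         scatter_offset_range = c(-0.1, 0.1),
                         noise_sd = 0.003,
                         noise_window = c(710, 985),
                         noise_edge_factor = 7, seed = 1) {
  if (n_samples < 4) abort("`n_samples` must be >= 4.", class = "fujigrade_invalid_parameter")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "fujigrade_invalid_parameter")
  if (any(band_centers < wl_range[1]) || any(band_centers > wl_range[2])) {
    abort("`band_centers` must lie inside `wl_range`.", class = "fujigrade_invalid_parameter")
  }
  structure(
    list(n_samples = n_samples, n_wavelengths = n_wavelengths,
         wl_range = wl_range, brix_mean = brix_mean, brix_sd = brix_sd,
         brix_range = brix_range, band_centers = band_centers,
         band_widths = band_widths, band_gains = band_gains,
         band_noise_sd = band_noise_sd,
         interferent_centers = interferent_centers,
         interferent_widths = interferent_widths,
         interferent_sd = interferent_sd,
         n_clutter = n_clutter, clutter_sd = clutter_sd,
         clutter_wl_range = clutter_wl_range,
         clutter_width_range = clutter_width_range,
         scatter_on = scatter_on,
         scatter_slope_range = scatter_slope_range,
         scatter_offset_range = scatter_offset_range,
         noise_sd = noise_sd, noise_window = noise_window,
         noise_edge_factor = noise_edge_factor, seed = seed),
    class = "spectra_spec"
  )
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulate diffuse-reflectance apple spectra with a planted Brix signal
#'
#' Generates a [spectra_set()] according to a [spectra_spec()]; see that
#' help page for the generative model. The component shapes (baseline,
#' absorption-band and interferent profiles) are attached as attribute
#' `"basis"` so tests can verify that noise-free spectra lie exactly in
#' their affine span.
#'
#' @param spec A [spectra_spec()].
#' @return A list with `spectra` (a `spectra_set` carrying the true
#'   Brix values) and `truth` (tibble of per-sample Brix, scatter
#'   coefficients and interferent amplitudes).
#' @examples
#' sim <- simulate_spectra(spectra_spec(n_samples = 8, n_wavelengths = 120, seed = 3))
#' sim$spectra
#' @export
simulate_spectra <- function(spec) {
  stopifnot(inherits(spec, "spectra_spec"))
  wl <- seq(spec$wl_range[1], spec$wl_range[2], length.out = spec$n_wavelengths)
  baseline <- 0.45 + 0.22 * exp(-0.5 * ((wl - 620) / 190)^2) +
    0.08 * (wl - spec$wl_range[1]) / diff(spec$wl_range)
  bands <- sapply(seq_along(spec$band_centers), function(b) {
    exp(-0.5 * ((wl - spec$band_centers[b]) / spec$band_widths[b])^2)
  })
  interf <- sapply(seq_along(spec$interferent_centers), function(b) {
    exp(-0.5 * ((wl - spec$interferent_centers[b]) / spec$interferent_widths[b])^2)
  })

  with_local_seed(spec$seed, {
    n <- spec$n_samples
    brix <- rtruncnorm1(n, spec$brix_mean, spec$brix_sd,
                        spec$brix_range[1], spec$brix_range[2])
    amp <- matrix(abs(rnorm(n * ncol(interf), sd = spec$interferent_sd)),
                  nrow = n)
    depth_arg <- outer(brix, rep(1, ncol(bands))) +
      matrix(rnorm(n * ncol(bands), sd = spec$band_noise_sd), n)
    signal <- depth_arg * matrix(spec$band_gains, n, ncol(bands), byrow = TRUE)
    clean <- matrix(baseline, n, length(wl), byrow = TRUE) -
      signal %*% t(bands) - amp %*% t(interf)
    clutter_basis <- NULL
    if (spec$n_clutter > 0 && spec$clutter_sd > 0) {
      cc <- runif(spec$n_clutter, spec$clutter_wl_range[1], spec$clutter_wl_range[2])
      cw <- runif(spec$n_clutter, spec$clutter_width_range[1], spec$clutter_width_range[2])
      clutter_basis <- sapply(seq_len(spec$n_clutter), function(j) {
        exp(-0.5 * ((wl - cc[j]) / cw[j])^2)
      })
      camp <- matrix(rnorm(n * spec$n_clutter, sd = spec$clutter_sd), nrow = n)
      clean <- clean - camp %*% t(clutter_basis)
    }

    if (spec$scatter_on) {
      b_i <- runif(n, spec$scatter_slope_range[1], spec$scatter_slope_range[2])
      a_i <- runif(n, spec$scatter_offset_range[1], spec$scatter_offset_range[2])
    } else {
      b_i <- rep(1, n); a_i <- rep(0, n)
    }
    observed <- clean * b_i + a_i
    if (spec$noise_sd > 0) {
      sd_wl <- rep(spec$noise_sd, length(wl))
      outside <- wl < spec$noise_window[1] | wl > spec$noise_window[2]
      sd_wl[outside] <- spec$noise_sd * spec$noise_edge_factor
      observed <- observed + matrix(rnorm(n * length(wl)), n, length(wl)) *
        matrix(sd_wl, n, length(wl), byrow = TRUE)
    }
    ss <- spectra_set(wl, observed, brix = brix)
    attr(ss, "basis") <- cbind(baseline = baseline, bands, interf, clutter_basis)
    truth <- tibble(sample_id = ss$sample_ids, brix = brix,
                    scatter_slope = b_i, scatter_offset = a_i)
    for (j in seq_len(ncol(amp))) {
      truth[[paste0("interferent_amp", j)]] <- amp[, j]
    }
    list(spectra = ss, truth = truth)
  })
}
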