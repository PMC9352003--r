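#' Construct a set of reflectance spectra
#'
#' The container used throughout the chemometrics pipeline: a common
#' wavelength grid, an `N x W` reflectance matrix (samples in rows), and
#' an optional per-sample reference Brix vector.
#'
#' @param wavelengths Strictly increasing numeric grid, nm.
#' @param reflectance `N x W` numeric matrix of reflectance fractions;
#'   a single spectrum may be given as a vector.
#' @param brix Optional length-N numeric vector of reference soluble
#'   solids, °Brix.
#' @param sample_ids Optional character vector of sample identifiers
#'   (defaults to `s001, s002, ...`).
#' @return An object of class `spectra_set`.
#' @examples
#' ss <- spectra_set(400:409, matrix(runif(20), nrow = 2))
#' ss
#' @export
spectra_set <- function(wavelengths, reflectance, brix = NULL, sample_ids = NULL) {
  if (is.vector(reflectance)) reflectance <- matrix(reflectance, nrow = 1)
  if (any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be strictly increasing.", class = "fujigrade_invalid_parameter")
  }
  if (ncol(reflectance) != length(wavelengths)) {
    abort("`reflectance` must have one column per wavelength.",
          class = "fujigrade_invalid_parameter")
  }
  if (any(!is.finite(reflectance))) {
    abort("`reflectance` must be finite.", class = "fujigrade_invalid_parameter")
  }
  n <- nrow(reflectance)
  if (!is.null(brix) && length(brix) != n) {
    abort("`brix` must have one value per sample.", class = "fujigrade_invalid_parameter")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(n))
  rownames(reflectance) <- sample_ids
  structure(
    list(wavelengths = as.numeric(wavelengths), reflectance = reflectance,
         brix = brix, sample_ids = sample_ids),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$reflectance), " samples x ",
      length(x$wavelengths), " wavelengths (",
      min(x$wavelengths), "-", max(x$wavelengths), " nm)",
      if (!is.null(x$brix)) ", with reference Brix" else "", "\n", sep = "")
  invisible(x)
}

#' @method as_tibble spectra_set
#' @export
as_tibble.spectra_set <- function(x, ...) {
  out <- as_tibble(x$reflectance, .name_repair = "minimal")
  names(out) <- as.character(x$wavelengths)
  out <- mutate(out, sample_id = x$sample_ids, .before = 1)
  if (!is.null(x$brix)) out <- mutate(out, brix = x$brix, .after = "sample_id")
  tidyr::pivot_longer(out, cols = -dplyr::any_of(c("sample_id", "brix")),
                      names_to = "wavelength_nm", values_to = "reflectance") |>
    mutate(wavelength_nm = as.numeric(.data$wavelength_nm))
}

#' Black/white reflectance correction
#'
#' Converts raw detector counts to reflectance with a white-reference and
#' dark-reference measurement: `R = (I - I_d) / (I_w - I_d)`, elementwise
#' over the wavelength grid.
#'
#' @param raw Data frame with numeric columns `wavelength_nm`,
#'   `intensity` (sample counts `I`), `white_reference` (`I_w`) and
#'   `dark_reference` (`I_d`).
#' @return A tibble with columns `wavelength_nm` and `reflectance`.
#' @examples
#' raw <- tibble::tibble(wavelength_nm = 1:3, intensity = c(5, 10, 15),
#'                       white_reference = 20, dark_reference = 0)
#' reflectance_correct(raw)
#' @export
reflectance_correct <- function(raw) {
  need <- c("wavelength_nm", "intensity", "white_reference", "dark_reference")
  if (!all(need %in% names(raw))) {
    abort(paste("`raw` needs columns:", paste(need, collapse = ", ")),
          class = "fujigrade_invalid_parameter")
  }
  denom <- raw$white_reference - raw$dark_reference
  if (any(denom == 0)) {
    abort("White and dark references coincide at some wavelength; correction undefined.",
          class = "fujigrade_degenerate_reference")
  }
  tibble(wavelength_nm = raw$wavelength_nm,
         reflectance = (raw$intensity - raw$dark_reference) / denom)
}

#' Decimate the wavelength grid
#'
#' Keeps every `keep_every`-th wavelength starting from the first
#' (indices 1, 1 + s, 1 + 2s, ...), thinning both the grid and the
#' reflectance columns. A 1771-point 400-1000 nm grid decimated with
#' stride 3 leaves 591 points.
#'
#' @param spectra A [spectra_set()].
#' @param keep_every Integer stride `>= 1` (1 is the identity).
#' @return A decimated `spectra_set`.
#' @export
downsample_wavelengths <- function(spectra, keep_every = 3) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (!is.numeric(keep_every) || length(keep_every) != 1 || keep_every < 1 ||
      keep_every != round(keep_every)) {
    abort("`keep_every` must be a positive integer.", class = "fujigrade_invalid_parameter")
  }
  idx <- seq(1, length(spectra$wavelengths), by = keep_every)
  spectra_set(spectra$wavelengths[idx],
              spectra$reflectance[, idx, drop = FALSE],
              brix = spectra$brix, sample_ids = spectra$sample_ids)
}

#' Multiplicative scatter correction
#'
#' Removes scatter-induced offset and slope differences between spectra.
#' Each spectrum is regressed on a reference spectrum,
#' `R_i = a_i + b_i * ref + e`, and corrected as `(R_i - a_i) / b_i`. The
#' default reference is the mean spectrum of the set.
#'
#' @param spectra A [spectra_set()] with at least 2 samples (or an
#'   explicit `reference`).
#' @param reference Optional numeric reference spectrum (length W).
#' @return A corrected `spectra_set`; the reference used is attached as
#'   attribute `"msc_reference"`.
#' @export
msc <- function(spectra, reference = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  R <- spectra$reflectance
  if (is.null(reference)) {
    if (nrow(R) < 2) {
      abort("MSC needs >= 2 samples when no reference is supplied.",
            class = "fujigrade_invalid_parameter")
    }
    reference <- colMeans(R)
  }
  if (length(reference) != ncol(R)) {
    abort("`reference` length must match the wavelength grid.",
          class = "fujigrade_invalid_parameter")
  }
  if (sd(reference) == 0) {
    abort("Reference spectrum has zero variance; MSC undefined.",
          class = "fujigrade_degenerate_reference")
  }
  ref_c <- reference - mean(reference)
  denom <- sum(ref_c^2)
  corrected <- t(apply(R, 1, function(r) {
    b <- sum((r - mean(r)) * ref_c) / denom
    a <- mean(r) - b * mean(reference)
    (r - a) / b
  }))
  out <- spectra_set(spectra$wavelengths, corrected, brix = spectra$brix,
                     sample_ids = spectra$sample_ids)
  attr(out, "msc_reference") <- reference
  out
}

#' Standard normal variate transform
#'
#' Standardizes each spectrum independently across wavelengths to mean 0
#' and standard deviation 1, removing per-sample baseline and gain.
#'
#' @param spectra A [spectra_set()]; every spectrum must have nonzero
#'   standard deviation.
#' @return A transformed `spectra_set`.
#' @export
snv <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  R <- spectra$reflectance
  sds <- apply(R, 1, sd)
  if (any(sds == 0)) {
    abort("Constant spectrum encountered; SNV undefined.",
          class = "fujigrade_degenerate_spectrum")
  }
  corrected <- (R - rowMeans(R)) / sds
  spectra_set(spectra$wavelengths, corrected, brix = spectra$brix,
              sample_ids = spectra$sample_ids)
}

#' Brix grade classifier
#'
#' Grades soluble-solids content into high / medium / low:
#' `>= 13` °Brix high, `[10, 13)` medium, `< 10` low.
#'
#' @param brix Numeric °Brix value(s), `>= 0` (vectorized).
#' @return Character vector in `c("high", "medium", "low")`.
#' @export
classify_brix <- function(brix) {
  if (any(!is.finite(brix)) || any(brix < 0)) {
    abort("`brix` must be non-negative.", class = "fujigrade_invalid_parameter")
  }
  dplyr::case_when(brix >= 13 ~ "high", brix >= 10 ~ "medium", TRUE ~ "low")
}
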