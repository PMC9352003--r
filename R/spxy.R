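#' SPXY calibration/prediction partitioning
#'
#' Sample-set partitioning based on joint x-y distance. Pairwise distances
#' are the sum of the Euclidean distance on the spectra and the absolute
#' difference on Brix, each normalized by its maximum over all pairs:
#' `d_xy(p, q) = d_x(p, q) / max d_x + d_y(p, q) / max d_y`.
#' Calibration samples are accreted Kennard-Stone style: the pair with the
#' greatest joint distance seeds the set, then the sample whose minimum
#' joint distance to the selected set is largest is added until the
#' calibration size `round(N * cal / (cal + pred))` is reached. The
#' leftover samples form the prediction set, which therefore sits inside
#' the space spanned by the calibration set.
#'
#' @param spectra A [spectra_set()] with reference `brix` and `N >= 4`.
#' @param ratio Calibration:prediction ratio, either a single number `r`
#'   (meaning `r:1`) or a length-2 vector `c(cal, pred)`. Default 3:1.
#' @return A list with integer index vectors `cal` and `pred`
#'   (disjoint, union `1:N`), both sorted.
#' @examples
#' ss <- simulate_spectra(spectra_spec(n_samples = 20, n_wavelengths = 60, seed = 1))$spectra
#' sp <- spxy_split(ss)
#' lengths(sp)
#' @export
spxy_split <- function(spectra, ratio = 3) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (is.null(spectra$brix)) {
    abort("SPXY needs reference Brix values.", class = "fujigrade_missing_reference")
  }
  if (length(ratio) == 1) ratio <- c(ratio, 1)
  n <- nrow(spectra$reflectance)
  if (n < 4) abort("SPXY needs at least 4 samples.", class = "fujigrade_invalid_parameter")
  n_cal <- round(n * ratio[1] / sum(ratio))
  n_cal <- min(max(n_cal, 2L), n - 1L)

  dx <- as.matrix(stats::dist(spectra$reflectance))
  dy <- abs(outer(spectra$brix, spectra$brix, "-"))
  dxy <- dx / max(dx) + dy / max(dy)

  # seed with the farthest pair, then farthest-point accretion
  seed_pair <- which(dxy == max(dxy), arr.ind = TRUE)[1, ]
  selected <- as.integer(seed_pair)
  while (length(selected) < n_cal) {
    remaining <- setdiff(seq_len(n), selected)
    min_d <- apply(dxy[remaining, selected, drop = FALSE], 1, min)
    selected <- c(selected, remaining[which.max(min_d)])
  }
  list(cal = sort(selected), pred = sort(setdiff(seq_len(n), selected)))
}
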