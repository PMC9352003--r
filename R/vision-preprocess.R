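#' Gamma transform of an RGB image
#'
#' Contrast enhancement by the power law `v -> 255 * (v / 255)^gamma`,
#' applied per channel and rounded back to the 8-bit grid. `gamma < 1`
#' brightens mid-tones, `gamma > 1` darkens them; 0 and 255 are fixed
#' points for every exponent.
#'
#' @param image Height x width x 3 numeric array with values in `[0, 255]`.
#' @param gamma Positive exponent.
#' @return An array of the same dimensions on the 8-bit grid.
#' @examples
#' img <- array(64, dim = c(2, 2, 3))
#' gamma_correct(img, 0.5)[1, 1, 1]  # 128
#' @export
gamma_correct <- function(image, gamma) {
  check_rgb_image(image)
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) || gamma <= 0) {
    abort("`gamma` must be a single positive number.", class = "fujigrade_invalid_parameter")
  }
  out <- round(255 * (image / 255)^gamma)
  storage.mode(out) <- "double"
  out
}

# Reflective-boundary 1-D smoothing matrix: row i holds the Gaussian weights
# of output pixel i, with out-of-range taps folded back by half-sample
# mirror reflection (edge pixel repeated). That fold makes the matrix
# symmetric, so constants and total intensity are both preserved exactly.
gaussian_band_matrix <- function(n, sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  offsets <- -radius:radius
  w <- dnorm(offsets, sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offsets
    for (rep in 1:2) {           # fold twice in case radius > n
      j <- ifelse(j < 1, 1 - j, j)
      j <- ifelse(j > n, 2 * n + 1 - j, j)
    }
    j <- pmin(pmax(j, 1L), n)
    for (k in seq_along(j)) K[i, j[k]] <- K[i, j[k]] + w[k]
  }
  K
}

#' Gaussian smoothing of an RGB image
#'
#' Separable convolution of each channel with a normalized Gaussian kernel
#' (truncated at three sigma), using mirror reflection at the image border so
#' that total intensity is conserved. Used to suppress sensor noise while
#' keeping fruit contours sharp enough for boundary tracing.
#'
#' @inheritParams gamma_correct
#' @param sigma Kernel standard deviation in pixels (`> 0`).
#' @return A smoothed array of identical dimensions (not re-quantized).
#' @export
gaussian_smooth <- function(image, sigma) {
  check_rgb_image(image)
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    abort("`sigma` must be a single positive number.", class = "fujigrade_invalid_parameter")
  }
  d <- dim(image)
  Kr <- gaussian_band_matrix(d[1], sigma)
  Kc <- gaussian_band_matrix(d[2], sigma)
  out <- image
  for (ch in 1:3) out[, , ch] <- Kr %*% image[, , ch] %*% t(Kc)
  out
}

# standard Rec. 601 luminance, 8-bit scale
luminance <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}
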