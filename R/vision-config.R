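#' Configuration for the appearance-measurement pipeline
#'
#' Collects every tunable threshold used by the vision stage: preprocessing
#' parameters (gamma exponent, Gaussian smoothing sigma), the HSV rule that
#' separates the light background from the fruit, the morphological kernel
#' radius, the grey-level threshold under which a pixel inside the fruit is
#' counted as defective, and the three classifier thresholds (critical defect
#' ratio, round aspect-ratio band, size thresholds in pixels).
#'
#' Defaults follow the grading rules for Red Fuji apples: a defect pixel
#' ratio of `t0 = 0.0018` (a 3 mm spot on a 70 mm fruit), a nearly-round
#' aspect-ratio band of `[0.98, 1.05)`, and size thresholds of 164/139/127
#' pixels corresponding to 80/70/65 mm cross-sectional diameters under the
#' reference pixel-to-mm calibration.
#'
#' @param gamma Gamma-transform exponent applied before segmentation
#'   (`> 0`; `1` disables the transform).
#' @param gaussian_sigma Standard deviation, in pixels, of the Gaussian
#'   smoothing kernel (`> 0`).
#' @param hsv_s_max,hsv_v_min Background rule on the HSV transform:
#'   a pixel with saturation `<= hsv_s_max` and value `>= hsv_v_min`
#'   (both on `[0, 1]`) is treated as the light background.
#' @param morph_kernel Radius, in pixels, of the disc structuring element
#'   used for morphological opening and closing.
#' @param defect_grey_threshold 8-bit luminance level; pixels inside the
#'   fruit darker than this are counted as surface defect.
#' @param defect_ratio_cutoff Critical defect pixel ratio `t0`; fruit with
#'   `t >= t0` are labelled defective.
#' @param round_band Length-2 numeric, the half-open aspect-ratio interval
#'   `[low, high)` labelled nearly round.
#' @param size_thresholds_px Strictly decreasing length-3 integer vector of
#'   pixel thresholds separating extra-large/large/medium/small.
#'
#' @return An object of class `vision_config` (a named list).
#' @examples
#' cfg <- vision_config()
#' cfg$size_thresholds_px
#' @export
vision_config <- function(gamma = 1.2,
                          gaussian_sigma = 1.0,
                          hsv_s_max = 0.40,
                          hsv_v_min = 0.60,
                          morph_kernel = 3,
                          defect_grey_threshold = 55,
                          defect_ratio_cutoff = 0.0018,
                          round_band = c(0.98, 1.05),
                          size_thresholds_px = c(164, 139, 127)) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    abort("`gamma` must be a single positive number.", class = "fujigrade_invalid_parameter")
  }
  if (!is.numeric(gaussian_sigma) || length(gaussian_sigma) != 1 || gaussian_sigma <= 0) {
    abort("`gaussian_sigma` must be a single positive number.", class = "fujigrade_invalid_parameter")
  }
  if (defect_ratio_cutoff <= 0) {
    abort("`defect_ratio_cutoff` must be positive.", class = "fujigrade_invalid_parameter")
  }
  if (length(round_band) != 2 || round_band[1] >= round_band[2]) {
    abort("`round_band` must be (low, high) with low < high.", class = "fujigrade_invalid_parameter")
  }
  if (length(size_thresholds_px) != 3 || any(diff(size_thresholds_px) >= 0)) {
    abort("`size_thresholds_px` must be three strictly decreasing values.",
          class = "fujigrade_invalid_parameter")
  }
  structure(
    list(
      gamma = gamma,
      gaussian_sigma = gaussian_sigma,
      hsv_s_max = hsv_s_max,
      hsv_v_min = hsv_v_min,
      morph_kernel = morph_kernel,
      defect_grey_threshold = defect_grey_threshold,
      defect_ratio_cutoff = defect_ratio_cutoff,
      round_band = round_band,
      size_thresholds_px = size_thresholds_px
    ),
    class = "vision_config"
  )
}

#' @export
print.vision_config <- function(x, ...) {
  cat("<vision_config>\n")
  cat("  preprocessing: gamma =", x$gamma, ", gaussian sigma =", x$gaussian_sigma, "px\n")
  cat("  background rule: S <=", x$hsv_s_max, "& V >=", x$hsv_v_min, "\n")
  cat("  morphology kernel radius:", x$morph_kernel, "px\n")
  cat("  defect grey threshold:", x$defect_grey_threshold, "/ 255\n")
  cat("  defect ratio cutoff t0:", x$defect_ratio_cutoff, "\n")
  cat("  round band: [", x$round_band[1], ",", x$round_band[2], ")\n")
  cat("  size thresholds (px):", paste(x$size_thresholds_px, collapse = " / "), "\n")
  invisible(x)
}

# internal validators shared by the vision operations -------------------------

check_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort(sprintf("`%s` must be a height x width x 3 numeric array.", arg),
          class = "fujigrade_invalid_parameter")
  }
  if (min(image) < 0 || max(image) > 255) {
    abort(sprintf("`%s` channel values must lie in [0, 255].", arg),
          class = "fujigrade_invalid_parameter")
  }
  invisible(image)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    abort(sprintf("`%s` must be a binary (0/1) matrix.", arg),
          class = "fujigrade_invalid_parameter")
  }
  invisible(mask)
}
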