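#' Critical defect ratio from physical diameters
#'
#' The area ratio of a circular defect of diameter `d0_mm` on a fruit of
#' cross-sectional diameter `d1_mm`: `(d0/d1)^2`. With the reference
#' choice of a 3 mm minimum visible spot on a 70 mm fruit this gives the
#' default classifier cutoff `t0 = (3/70)^2 ~ 0.0018` (0.18%).
#'
#' @param d0_mm Defect spot diameter, mm (`> 0`).
#' @param d1_mm Fruit cross-sectional diameter, mm (`> 0`).
#' @return The dimensionless critical area fraction.
#' @examples
#' critical_defect_ratio(3, 70) * 100  # percent
#' @export
critical_defect_ratio <- function(d0_mm = 3, d1_mm = 70) {
  if (d0_mm <= 0 || d1_mm <= 0) {
    abort("Diameters must be positive.", class = "fujigrade_invalid_parameter")
  }
  (d0_mm / d1_mm)^2
}

#' Defect classifier
#'
#' Labels a fruit from its defective pixel ratio `t`: normal when
#' `t < t0`, defective when `t >= t0` (the critical ratio `t0` defaults to
#' 0.0018, the area ratio of a 3 mm spot on a 70 mm fruit).
#'
#' @param t Defective pixel ratio(s) in `[0, 1]` (vectorized).
#' @param config A [vision_config()].
#' @return Character vector, `"normal"` or `"defective"`.
#' @export
classify_defect <- function(t, config = vision_config()) {
  if (any(!is.finite(t)) || any(t < 0) || any(t > 1)) {
    abort("Defect ratio `t` must lie in [0, 1].", class = "fujigrade_invalid_parameter")
  }
  ifelse(t >= config$defect_ratio_cutoff, "defective", "normal")
}

#' Shape classifier
#'
#' Labels a fruit from its aspect ratio `lambda`: nearly round when
#' `lambda` lies in the half-open round band `[0.98, 1.05)`, nearly oval
#' otherwise.
#'
#' @param lambda Aspect ratio(s), `> 0` (vectorized).
#' @inheritParams classify_defect
#' @return Character vector, `"nearly_round"` or `"nearly_oval"`.
#' @export
classify_shape <- function(lambda, config = vision_config()) {
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    abort("Aspect ratio `lambda` must be positive.", class = "fujigrade_invalid_parameter")
  }
  ifelse(lambda >= config$round_band[1] & lambda < config$round_band[2],
         "nearly_round", "nearly_oval")
}

#' Size classifier
#'
#' Grades a fruit from the maximum cross-sectional diameter `W_p` of its
#' image, in pixels, against three decreasing thresholds (defaults
#' 164/139/127 px, i.e. 80/70/65 mm under the reference calibration):
#' `W_p >= 164` extra-large, `[139, 164)` large, `[127, 139)` medium,
#' `< 127` small.
#'
#' @param wp Diameter(s) in pixels, `>= 0` (vectorized).
#' @inheritParams classify_defect
#' @return Character vector in
#'   `c("extra_large", "large", "medium", "small")`.
#' @export
classify_size <- function(wp, config = vision_config()) {
  if (any(!is.finite(wp)) || any(wp < 0)) {
    abort("Diameter `wp` must be non-negative.", class = "fujigrade_invalid_parameter")
  }
  th <- config$size_thresholds_px
  dplyr::case_when(
    wp >= th[1] ~ "extra_large",
    wp >= th[2] ~ "large",
    wp >= th[3] ~ "medium",
    TRUE ~ "small"
  )
}

#' Measure and classify the appearance of one fruit image
#'
#' Runs the complete vision chain on a top-view RGB image: gamma
#' transform, Gaussian smoothing, HSV background segmentation with
#' morphological cleanup and hole filling, largest-contour extraction,
#' defect extraction, and the three appearance statistics with their
#' labels.
#'
#' @param image Height x width x 3 numeric array in `[0, 255]` (e.g. from
#'   [read_rgb_image()]).
#' @param config A [vision_config()].
#' @param masks If `TRUE`, attach the fruit and defect masks and the
#'   contour as an attribute `"masks"` for inspection/plotting.
#' @return A one-row tibble with columns `t` (defect pixel ratio),
#'   `lambda` (aspect ratio), `wp` (max cross diameter, px),
#'   `defect_label`, `shape_label`, `size_label`.
#' @examples
#' ap <- render_apple(image_spec(diameter_px = 120, seed = 1))
#' measure_apple(ap$image)
#' @export
measure_apple <- function(image, config = vision_config(), masks = FALSE) {
  check_rgb_image(image)
  pre <- gaussian_smooth(gamma_correct(image, config$gamma), config$gaussian_sigma)
  fruit <- segment_fruit(pre, config)
  if (sum(fruit) == 0) {
    abort("No fruit found in the image.", class = "fujigrade_no_fruit")
  }
  contour <- largest_contour(fruit)
  fruit_mask <- contour$mask
  defects <- extract_defects(pre, fruit_mask, config)
  t <- defect_ratio(defects, fruit_mask)
  lambda <- aspect_ratio(contour)
  wp <- max_cross_diameter(contour)
  out <- tibble(
    t = t,
    lambda = lambda,
    wp = wp,
    defect_label = classify_defect(t, config),
    shape_label = classify_shape(lambda, config),
    size_label = classify_size(wp, config)
  )
  if (masks) {
    attr(out, "masks") <- list(fruit = fruit_mask, defects = defects, contour = contour)
  }
  out
}
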