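# EBImage stores images with x (column) as the first dimension; the package
# convention is height x width matrices (row = y, col = x), so masks are
# transposed on the way in and out.
as_ebimage <- function(mask) EBImage::Image(t(mask))
from_ebimage <- function(img) {
  m <- t(EBImage::imageData(img))
  m[m != 0] <- 1
  storage.mode(m) <- "integer"
  m
}

#' Segment the fruit from a light background
#'
#' Converts the (preprocessed) RGB image to HSV and classifies
#' low-saturation, high-value pixels as the light background; the
#' complement is the fruit candidate region. Morphological opening then
#' closing with a disc structuring element removes small discrete
#' components and boundary interference, and interior holes (specular
#' highlights, the fruit tip) are filled.
#'
#' @param image Height x width x 3 array in `[0, 255]`, already gamma
#'   corrected and smoothed (see [measure_apple()] for the full chain).
#' @param config A [vision_config()].
#' @return A binary height x width matrix: 1 = fruit, 0 = background.
#'   An all-background image yields an all-zero mask.
#' @export
segment_fruit <- function(image, config = vision_config()) {
  check_rgb_image(image)
  d <- dim(image)
  hsv <- rgb2hsv(r = as.vector(image[, , 1]),
                 g = as.vector(image[, , 2]),
                 b = as.vector(image[, , 3]), maxColorValue = 255)
  background <- hsv["s", ] <= config$hsv_s_max & hsv["v", ] >= config$hsv_v_min
  mask <- matrix(as.integer(!background), nrow = d[1], ncol = d[2])
  if (sum(mask) == 0) return(mask)
  brush <- EBImage::makeBrush(2 * config$morph_kernel + 1, shape = "disc")
  img <- as_ebimage(mask)
  img <- EBImage::closing(EBImage::opening(img, brush), brush)
  img <- EBImage::fillHull(img)
  from_ebimage(img)
}

# label 8-connected components; returns height x width integer matrix of labels
label_components <- function(mask) {
  lab <- EBImage::bwlabel(as_ebimage(mask))
  t(EBImage::imageData(lab))
}

# mask restricted to the connected component with the largest pixel area
largest_component <- function(mask) {
  labels <- label_components(mask)
  counts <- tabulate(labels[labels > 0])
  best <- which.max(counts)
  out <- matrix(as.integer(labels == best), nrow = nrow(mask))
  out
}

#' Extract the largest closed contour of a binary mask
#'
#' Traces the boundary of the connected component with the greatest pixel
#' area (Moore boundary following, 8-connectivity) and returns it as an
#' ordered closed polygon of 1-based pixel coordinates together with the
#' component's moment centroid. This is the fruit boundary used by the
#' shape and size classifiers.
#'
#' @param mask Binary height x width matrix with at least one foreground
#'   pixel.
#' @return An object of class `contour_polygon`: a list with `points`
#'   (n x 2 matrix, columns `x`, `y`), `centroid` (`c(x_c, y_c)`, sub-pixel)
#'   and `mask` (the component's filled mask).
#' @export
largest_contour <- function(mask) {
  check_mask(mask)
  if (sum(mask) == 0) {
    abort("Mask contains no foreground pixels; no contour to extract.",
          class = "fujigrade_no_contour")
  }
  comp <- largest_component(mask)
  oc <- EBImage::ocontour(as_ebimage(comp))[[1]]
  pts <- cbind(x = oc[, 1] + 1, y = oc[, 2] + 1)  # ocontour is 0-based
  structure(
    list(points = pts, centroid = contour_centroid(comp), mask = comp),
    class = "contour_polygon"
  )
}

#' @export
print.contour_polygon <- function(x, ...) {
  cat("<contour_polygon> ", nrow(x$points), " boundary points, centroid (",
      round(x$centroid[1], 2), ", ", round(x$centroid[2], 2), ")\n", sep = "")
  invisible(x)
}

#' Extract candidate defect pixels inside the fruit
#'
#' Surface defects (rot, scars, wormholes, bruises) appear darker than
#' healthy peel. Pixels inside the fruit mask whose Rec. 601 luminance
#' falls below `config$defect_grey_threshold` are flagged; the result is
#' always a subset of the fruit mask.
#'
#' @param image Preprocessed RGB array (same one used for segmentation).
#' @param fruit_mask Binary matrix from [segment_fruit()] /
#'   [largest_contour()]; must be non-empty.
#' @param config A [vision_config()].
#' @return Binary defect mask of the same dimensions.
#' @export
extract_defects <- function(image, fruit_mask, config = vision_config()) {
  check_rgb_image(image)
  check_mask(fruit_mask, "fruit_mask")
  if (sum(fruit_mask) == 0) {
    abort("Fruit mask is empty; nothing to inspect for defects.",
          class = "fujigrade_no_fruit")
  }
  grey <- luminance(image)
  out <- matrix(as.integer(grey < config$defect_grey_threshold & fruit_mask == 1),
                nrow = nrow(fruit_mask))
  out
}

#' Defective pixel ratio
#'
#' The fraction `t` of fruit pixels flagged as defective: the statistic the
#' defect classifier thresholds against the critical ratio `t0`.
#'
#' @param defect_mask Binary matrix, a subset of `fruit_mask`.
#' @param fruit_mask Binary matrix with at least one foreground pixel.
#' @return A single number in `[0, 1]`.
#' @export
defect_ratio <- function(defect_mask, fruit_mask) {
  check_mask(defect_mask, "defect_mask")
  check_mask(fruit_mask, "fruit_mask")
  n_fruit <- sum(fruit_mask)
  if (n_fruit == 0) {
    abort("Fruit mask is empty; defect ratio undefined.",
          class = "fujigrade_division_undefined")
  }
  if (any(defect_mask == 1 & fruit_mask == 0)) {
    abort("`defect_mask` must be a subset of `fruit_mask`.",
          class = "fujigrade_invalid_parameter")
  }
  sum(defect_mask) / n_fruit
}
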