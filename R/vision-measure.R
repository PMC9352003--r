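#' Raw image moments
#'
#' The (p + q)-order raw moment of a binary (or grey) image,
#' `m_pq = sum_y sum_x x^p * y^q * f(x, y)`, with 1-based pixel coordinates
#' (x = column, y = row). `m_00` of a binary mask is its area in pixels;
#' first-order moments give the centroid.
#'
#' @param mask Numeric height x width matrix (`f(x, y)`).
#' @param p,q Non-negative integer orders.
#' @return A single number.
#' @examples
#' m <- matrix(1, 3, 3)
#' raw_moment(m, 0, 0)  # area = 9
#' @export
raw_moment <- function(mask, p, q) {
  if (!is.matrix(mask)) {
    abort("`mask` must be a matrix.", class = "fujigrade_invalid_parameter")
  }
  if (p < 0 || q < 0) {
    abort("Moment orders must be non-negative.", class = "fujigrade_invalid_parameter")
  }
  y <- seq_len(nrow(mask))^q
  x <- seq_len(ncol(mask))^p
  drop(t(y) %*% mask %*% x)
}

#' Centroid of a binary mask
#'
#' Contour centre `(x_c, y_c) = (m_10 / m_00, m_01 / m_00)` from the raw
#' moments of the filled region.
#'
#' @param mask Binary height x width matrix with `m_00 > 0`.
#' @return Numeric `c(x_c, y_c)` in sub-pixel 1-based coordinates.
#' @export
contour_centroid <- function(mask) {
  check_mask(mask)
  m00 <- raw_moment(mask, 0, 0)
  if (m00 == 0) {
    abort("Mask is empty; centroid undefined.", class = "fujigrade_division_undefined")
  }
  c(x_c = raw_moment(mask, 1, 0) / m00, y_c = raw_moment(mask, 0, 1) / m00)
}

#' Aspect ratio of a fruit contour
#'
#' The ratio `lambda` of the maximum horizontal extent to the maximum
#' vertical extent of the contour points — near 1 for a round fruit.
#'
#' @param contour A `contour_polygon` from [largest_contour()], or an
#'   n x 2 matrix of `(x, y)` points.
#' @return A single positive number.
#' @export
aspect_ratio <- function(contour) {
  pts <- if (inherits(contour, "contour_polygon")) contour$points else contour
  if (!is.matrix(pts) || nrow(pts) < 3) {
    abort("Contour must have at least 3 points.", class = "fujigrade_degenerate_contour")
  }
  dx <- max(pts[, 1]) - min(pts[, 1])
  dy <- max(pts[, 2]) - min(pts[, 2])
  if (dy == 0) {
    abort("Contour has zero vertical extent; aspect ratio undefined.",
          class = "fujigrade_degenerate_contour")
  }
  dx / dy
}

#' Maximum cross-sectional diameter in pixels
#'
#' Radius sequence `r_k = sqrt((x_k - x_c)^2 + (y_k - y_c)^2)` from the
#' contour centroid to the boundary, restricted to the vertices of the
#' contour's convex hull (the maximum centroid-to-boundary distance is
#' always attained on the hull), and `W_p = 2 * max(r_k)`.
#'
#' @inheritParams aspect_ratio
#' @param centroid Optional `c(x_c, y_c)`; defaults to the contour's own
#'   centroid.
#' @return `W_p` in pixels (0 for a degenerate single-point contour).
#' @export
max_cross_diameter <- function(contour, centroid = NULL) {
  pts <- if (inherits(contour, "contour_polygon")) contour$points else contour
  if (is.null(centroid) && inherits(contour, "contour_polygon")) {
    centroid <- contour$centroid
  }
  if (!is.matrix(pts) || nrow(pts) == 0) {
    abort("Contour has no points.", class = "fujigrade_degenerate_contour")
  }
  if (nrow(pts) == 1) return(0)
  if (is.null(centroid)) centroid <- colMeans(pts)
  hull <- chull(pts[, 1], pts[, 2])
  hx <- pts[hull, 1] - centroid[1]
  hy <- pts[hull, 2] - centroid[2]
  2 * sqrt(max(hx^2 + hy^2))
}
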