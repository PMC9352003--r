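#' Fit the pixel-to-millimetre size calibration
#'
#' Ordinary least-squares regression of caliper-measured maximum
#' cross-sectional diameters `Wr` (mm) on image diameters `Wp` (pixels),
#' `Wr = slope * Wp + intercept`. The reference calibration for the
#' grading thresholds is `Wr = 0.4052 * Wp + 13.5015`.
#'
#' @param pairs Data frame with numeric columns `wp` (pixels) and
#'   `wr` (mm); at least two rows with non-identical `wp`.
#' @return An object of class `size_calibration` with fields `slope`,
#'   `intercept`, `r_squared`, `residual_variance`, `n_pairs` and the
#'   underlying `lm` fit. Has [tidy()] and [glance()] methods.
#' @examples
#' pairs <- make_calibration_pairs(30, noise_sd = 0, seed = 1)
#' fit_size_calibration(pairs)
#' @export
fit_size_calibration <- function(pairs) {
  if (!all(c("wp", "wr") %in% names(pairs))) {
    abort("`pairs` needs columns `wp` and `wr`.", class = "fujigrade_invalid_parameter")
  }
  pairs <- as_tibble(pairs)
  if (nrow(pairs) < 2) {
    abort("Need at least two calibration pairs.", class = "fujigrade_invalid_parameter")
  }
  if (length(unique(pairs$wp)) < 2) {
    abort("All `wp` values identical; calibration fit is singular.",
          class = "fujigrade_singular_fit")
  }
  fit <- lm(wr ~ wp, data = pairs)
  res <- summary(fit)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = res$r.squared,
      residual_variance = res$sigma^2,
      n_pairs = nrow(pairs),
      fit = fit
    ),
    class = "size_calibration"
  )
}

#' The reference size calibration
#'
#' The fixed calibration `Wr = 0.4052 * Wp + 13.5015` (mm vs pixels) that
#' yields the default 164/139/127 px size thresholds.
#'
#' @return A `size_calibration` object (no underlying `lm`; exact line).
#' @export
reference_calibration <- function() {
  structure(
    list(slope = 0.4052, intercept = 13.5015, r_squared = 1,
         residual_variance = 0, n_pairs = 2L, fit = NULL),
    class = "size_calibration"
  )
}

#' @export
print.size_calibration <- function(x, ...) {
  cat("<size_calibration>  Wr =", format(x$slope, digits = 6), "* Wp +",
      format(x$intercept, digits = 6), "\n")
  cat("  R^2 =", format(x$r_squared, digits = 4),
      " residual variance =", format(x$residual_variance, digits = 4),
      " n =", x$n_pairs, "\n")
  invisible(x)
}

#' @rdname fit_size_calibration
#' @param x A `size_calibration` object.
#' @param ... Unused.
#' @method tidy size_calibration
#' @export
tidy.size_calibration <- function(x, ...) {
  if (!is.null(x$fit)) {
    out <- as_tibble(summary(x$fit)$coefficients, rownames = "term")
    names(out) <- c("term", "estimate", "std.error", "statistic", "p.value")
    out$term <- c("intercept", "slope")
    return(out)
  }
  tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope),
         std.error = NA_real_, statistic = NA_real_, p.value = NA_real_)
}

#' @rdname fit_size_calibration
#' @method glance size_calibration
#' @export
glance.size_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = sqrt(x$residual_variance),
         nobs = x$n_pairs)
}

#' Pixel thresholds from millimetre size cutoffs
#'
#' Inverts the size calibration, `Wp = (Wr - intercept) / slope`, at each
#' millimetre cutoff and rounds to the nearest integer pixel. With the
#' reference calibration and the national-standard cutoffs 80/70/65 mm
#' this gives 164/139/127 px.
#'
#' @param cal A `size_calibration`.
#' @param cutoffs_mm Numeric vector of diameter cutoffs in mm
#'   (default `c(80, 70, 65)`).
#' @return Integer vector of pixel thresholds, one per cutoff.
#' @examples
#' size_thresholds(reference_calibration())  # 164 139 127
#' @export
size_thresholds <- function(cal, cutoffs_mm = c(80, 70, 65)) {
  if (!inherits(cal, "size_calibration")) {
    abort("`cal` must be a size_calibration.", class = "fujigrade_invalid_parameter")
  }
  if (cal$slope == 0) {
    abort("Calibration slope is zero; cannot invert.", class = "fujigrade_inversion_error")
  }
  as.integer(round((cutoffs_mm - cal$intercept) / cal$slope))
}
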