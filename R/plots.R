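#' Plot a set of spectra
#'
#' Spaghetti plot of reflectance against wavelength, one line per
#' sample, coloured by Brix when reference values are present.
#'
#' @param object A [spectra_set()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectra_set
#' @export
autoplot.spectra_set <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm,
                                        y = .data$reflectance,
                                        group = .data$sample_id))
  if ("brix" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$brix), alpha = 0.6) +
      ggplot2::scale_colour_viridis_c(name = "°Brix")
  } else {
    p <- p + ggplot2::geom_line(alpha = 0.6)
  }
  p + ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance") +
    ggplot2::theme_minimal()
}

#' Plot a wavelength-selection criterion trace
#'
#' RMSECV per Monte-Carlo run (CARS) or RMSE per subset size (SPA), with
#' the selected optimum marked.
#'
#' @param object A `selection_result` from [cars_select()] or
#'   [spa_select()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  xvals <- if (!is.null(object$trace_sizes)) object$trace_sizes
           else seq_along(object$criterion_trace)
  df <- tibble(x = xvals, criterion = object$criterion_trace)
  best_x <- xvals[object$best_iteration]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$criterion)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = best_x, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = if (object$method == "SPA") "Subset size" else "Sampling run",
      y = if (object$method == "SPA") "RMSE (°Brix)" else "RMSECV (°Brix)",
      title = paste(object$method, "selection trace")
    ) +
    ggplot2::theme_minimal()
}

#' Predicted-versus-measured Brix scatter plot
#'
#' Calibration and prediction samples against the identity line, the
#' standard diagnostic for a chemometrics calibration.
#'
#' @param object A fitted `brix_model` (must retain its predictions,
#'   i.e. come from [fit_brix_model()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot brix_model
#' @export
autoplot.brix_model <- function(object, ...) {
  if (is.null(object$predictions)) {
    abort("Model carries no stored predictions (was it read from JSON?).",
          class = "fujigrade_invalid_parameter")
  }
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$brix, y = .data$brix_pred,
                               colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Measured °Brix", y = "Predicted °Brix",
                  title = toupper(object$method)) +
    ggplot2::theme_minimal()
}

#' Size-calibration scatter plot
#'
#' Calibration pairs with the fitted regression line `Wr = slope * Wp +
#' intercept`.
#'
#' @param object A `size_calibration` from [fit_size_calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot size_calibration
#' @export
autoplot.size_calibration <- function(object, ...) {
  if (is.null(object$fit)) {
    abort("Calibration carries no data points to plot.",
          class = "fujigrade_invalid_parameter")
  }
  df <- as_tibble(object$fit$model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wp, y = .data$wr)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = expression(W[p] ~ "(pixels)"),
                  y = expression(W[r] ~ "(mm)")) +
    ggplot2::theme_minimal()
}
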