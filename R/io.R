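#' Read an RGB image from a PNG file
#'
#' @param path PNG file path.
#' @return Height x width x 3 numeric array with values in `[0, 255]`
#'   (alpha dropped, greyscale replicated to three channels).
#' @export
read_rgb_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] == 4) px <- px[, , 1:3]
  px * 255
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask Binary height x width matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask * 1.0, path)   # writePNG needs doubles; 1 maps to 255
  invisible(path)
}

#' Write an RGB image array as PNG
#'
#' @param image Height x width x 3 array in `[0, 255]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  check_rgb_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read/write spectra as wide CSV
#'
#' The on-disk format is a wide table: first column `wavelength_nm`, one
#' column per sample (sample IDs as headers). An optional companion CSV
#' with columns `sample_id, brix` supplies reference values.
#'
#' @param path Spectra CSV path.
#' @param brix_path Optional Brix reference CSV path.
#' @return [read_spectra_csv()] returns a [spectra_set()];
#'   [write_spectra_csv()] returns `path` invisibly.
#' @export
read_spectra_csv <- function(path, brix_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm") {
    abort("First column must be `wavelength_nm`.", class = "fujigrade_invalid_parameter")
  }
  R <- t(as.matrix(df[, -1, drop = FALSE]))
  ids <- names(df)[-1]
  brix <- NULL
  if (!is.null(brix_path)) {
    b <- utils::read.csv(brix_path)
    if (!all(c("sample_id", "brix") %in% names(b))) {
      abort("Brix CSV needs columns `sample_id`, `brix`.",
            class = "fujigrade_invalid_parameter")
    }
    missing <- setdiff(ids, b$sample_id)
    if (length(missing) > 0) {
      abort(paste("No Brix value for sample(s):", paste(missing, collapse = ", ")),
            class = "fujigrade_pairing_error")
    }
    brix <- b$brix[match(ids, b$sample_id)]
  }
  spectra_set(df$wavelength_nm, R, brix = brix, sample_ids = ids)
}

#' @rdname read_spectra_csv
#' @param spectra A [spectra_set()].
#' @export
write_spectra_csv <- function(spectra, path, brix_path = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  df <- data.frame(wavelength_nm = spectra$wavelengths,
                   t(spectra$reflectance), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(brix_path)) {
    if (is.null(spectra$brix)) {
      abort("Spectra carry no Brix values to write.", class = "fujigrade_missing_reference")
    }
    utils::write.csv(data.frame(sample_id = spectra$sample_ids,
                                brix = spectra$brix),
                     brix_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write appearance results as JSON records
#'
#' @param appearance Tibble of [measure_apple()] rows (with an optional
#'   `sample_id` column).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_appearance_json <- function(appearance, path) {
  jsonlite::write_json(appearance, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
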