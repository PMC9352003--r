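#' Pipeline configuration
#'
#' Bundles the vision thresholds, the chemometrics options and the run
#' seed into one object that can round-trip through YAML. Unknown keys
#' in a YAML file are rejected rather than silently dropped.
#'
#' @param vision A [vision_config()] or a named list of its arguments.
#' @param chemometrics Named list of [fit_brix_model()] options
#'   (`method`, `stride`, `use_msc`, `use_snv`, `ratio`,
#'   `max_components`, `n_folds`, `cars_runs`, `spa_range`).
#' @param seed Integer seed for the whole run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(vision = vision_config(),
                            chemometrics = list(), seed = 1) {
  if (!inherits(vision, "vision_config")) {
    vision <- do.call(vision_config, vision)
  }
  chemo_defaults <- list(method = "cars-pls", stride = 3, use_msc = TRUE,
                         use_snv = TRUE, ratio = 3, max_components = 20,
                         n_folds = 10, cars_runs = 50, spa_range = c(30, 50))
  unknown <- setdiff(names(chemometrics), names(chemo_defaults))
  if (length(unknown) > 0) {
    abort(paste("Unknown chemometrics option(s):", paste(unknown, collapse = ", ")),
          class = "fujigrade_invalid_parameter")
  }
  chemo <- utils::modifyList(chemo_defaults, chemometrics)
  structure(list(vision = vision, chemometrics = chemo, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), c("vision", "chemometrics", "seed"))
  if (length(unknown) > 0) {
    abort(paste("Unknown config section(s):", paste(unknown, collapse = ", ")),
          class = "fujigrade_invalid_parameter")
  }
  vis <- raw$vision %||% list()
  unknown_v <- setdiff(names(vis), names(formals(vision_config)))
  if (length(unknown_v) > 0) {
    abort(paste("Unknown vision option(s):", paste(unknown_v, collapse = ", ")),
          class = "fujigrade_invalid_parameter")
  }
  pipeline_config(vision = do.call(vision_config, vis),
                  chemometrics = raw$chemometrics %||% list(),
                  seed = raw$seed %||% 1)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
pipeline_config_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(list(vision = unclass(config$vision),
                        chemometrics = config$chemometrics,
                        seed = config$seed), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full grading pipeline over a batch of fruit
#'
#' For each fruit: the appearance is measured from its image, the Brix
#' value is predicted from its spectrum with a fitted [fit_brix_model()]
#' and graded, and the comprehensive grading decision is applied. Images
#' and spectra are paired by shared sample ID; a mismatch is an error
#' that lists the offenders.
#'
#' @param images Named list of RGB arrays, or a character vector of PNG
#'   paths (IDs = file name stems).
#' @param spectra A [spectra_set()] on the raw grid whose `sample_ids`
#'   match the image IDs.
#' @param model A `brix_model` (fitted or [read_brix_model()]).
#' @param config A [pipeline_config()].
#' @return A tibble with one row per fruit: `sample_id`, the appearance
#'   measurements and labels, `brix_pred`, `brix_grade`,
#'   `quality_grade`, `size_grade`.
#' @export
run_pipeline <- function(images, spectra, model, config = pipeline_config()) {
  stopifnot(inherits(spectra, "spectra_set"), inherits(model, "brix_model"))
  if (is.character(images)) {
    ids <- sub("\\.[Pp][Nn][Gg]$", "", basename(images))
    images <- stats::setNames(lapply(images, read_rgb_image), ids)
  }
  if (length(images) == 0) {
    return(tibble(sample_id = character(), t = numeric(), lambda = numeric(),
                  wp = numeric(), defect_label = character(),
                  shape_label = character(), size_label = character(),
                  brix_pred = numeric(), brix_grade = character(),
                  quality_grade = character(), size_grade = character()))
  }
  ids <- names(images)
  only_img <- setdiff(ids, spectra$sample_ids)
  only_spec <- setdiff(spectra$sample_ids, ids)
  if (length(only_img) > 0 || length(only_spec) > 0) {
    abort(paste0(
      "Image/spectrum sample IDs do not pair up.",
      if (length(only_img) > 0) paste0(" Images without spectra: ",
                                       paste(only_img, collapse = ", "), "."),
      if (length(only_spec) > 0) paste0(" Spectra without images: ",
                                        paste(only_spec, collapse = ", "), ".")),
      class = "fujigrade_pairing_error")
  }
  appearance <- purrr::map_dfr(images, ~ measure_apple(.x, config$vision))
  appearance <- mutate(appearance, sample_id = ids, .before = 1)

  keep <- match(ids, spectra$sample_ids)
  sub <- spectra_set(spectra$wavelengths,
                     spectra$reflectance[keep, , drop = FALSE],
                     brix = spectra$brix[keep],
                     sample_ids = ids)
  brix_pred <- predict(model, sub)
  brix_grade <- classify_brix(pmax(brix_pred, 0))
  grades <- grade_apples(appearance, brix_grade)
  dplyr::bind_cols(
    appearance,
    tibble(brix_pred = as.numeric(brix_pred), brix_grade = brix_grade,
           quality_grade = grades$quality_grade,
           size_grade = grades$size_grade)
  )
}
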