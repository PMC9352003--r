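#' Comprehensive apple grading decision
#'
#' Combines the three appearance labels with the Brix grade into the
#' final quality grade, following the grading flow: any surface defect
#' makes the fruit substandard; a defect-free but nearly-oval fruit is
#' directly second class (its Brix is not consulted); a defect-free
#' nearly-round fruit is excellent / first class / second class for
#' high / medium / low Brix. The size grade is carried through unchanged
#' and never influences the quality grade.
#'
#' @param appearance Data frame with columns `defect_label`
#'   (`"normal"`/`"defective"`), `shape_label`
#'   (`"nearly_round"`/`"nearly_oval"`) and `size_label`
#'   (one of `"extra_large"`, `"large"`, `"medium"`, `"small"`), e.g.
#'   rows from [measure_apple()].
#' @param brix_grade Character vector (recycled if length 1) of Brix
#'   grades, `"high"`/`"medium"`/`"low"` (see [classify_brix()]).
#' @return A tibble with one row per fruit: `quality_grade` (one of
#'   `"excellent"`, `"first_class"`, `"second_class"`, `"substandard"`),
#'   `size_grade`, and the input labels echoed.
#' @examples
#' app <- tibble::tibble(defect_label = "normal", shape_label = "nearly_round",
#'                       size_label = "large")
#' grade_apples(app, "high")
#' @export
grade_apples <- function(appearance, brix_grade) {
  need <- c("defect_label", "shape_label", "size_label")
  if (!all(need %in% names(appearance))) {
    abort(paste("`appearance` needs columns:", paste(need, collapse = ", ")),
          class = "fujigrade_incomplete_input")
  }
  n <- nrow(appearance)
  if (length(brix_grade) == 1) brix_grade <- rep(brix_grade, n)
  if (length(brix_grade) != n) {
    abort("`brix_grade` must have one value per fruit.",
          class = "fujigrade_incomplete_input")
  }
  ok <- appearance$defect_label %in% c("normal", "defective") &
    appearance$shape_label %in% c("nearly_round", "nearly_oval") &
    appearance$size_label %in% c("extra_large", "large", "medium", "small") &
    brix_grade %in% c("high", "medium", "low")
  if (any(!ok | is.na(ok))) {
    abort("Missing or unrecognized label(s) in the grading inputs.",
          class = "fujigrade_incomplete_input")
  }
  quality <- dplyr::case_when(
    appearance$defect_label == "defective" ~ "substandard",
    appearance$shape_label == "nearly_oval" ~ "second_class",
    brix_grade == "high" ~ "excellent",
    brix_grade == "medium" ~ "first_class",
    TRUE ~ "second_class"
  )
  tibble(
    quality_grade = quality,
    size_grade = appearance$size_label,
    defect_label = appearance$defect_label,
    shape_label = appearance$shape_label,
    brix_grade = brix_grade
  )
}
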