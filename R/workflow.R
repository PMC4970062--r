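#' Run the full grading study on a calibration / validation split
#'
#' Reproduces the complete single-camera grading workflow on measurement
#' tables:
#' 1. fit the MiDES estimator on the calibration fruit by stepwise
#'    regression over the four measurable parameters,
#' 2. estimate MiDES for the validation fruit and grade them from weight
#'    and estimated MMR,
#' 3. compare against the actual classes (confusion table),
#' 4. fit discriminant lines in (length/MaDES, length/PA) space within the
#'    estimated Extra and estimated I groups and reclassify,
#' 5. compare again.
#'
#' @param calibration,validation Tibbles with the four measurable parameters
#'   plus `mides_mm` (calibration) and `actual` (validation), as produced by
#'   [sample_population()] / [make_validation_fixture()].
#' @param candidates Candidate predictors for the stepwise fit.
#' @param rule A [grade_rule()].
#' @return A list: `mides_fit` (`smlr_fit`), `graded` (validation tibble
#'   with `grade` and `grade_final`), `lines` (`grade_reclassifier`),
#'   `confusion_initial`, `confusion_final`.
#' @export
run_grading_study <- function(calibration, validation,
                              candidates = c("weight_g", "length_mm",
                                             "mades_mm", "pa_cm2"),
                              rule = grade_rule()) {
  mides_fit <- fit_smlr(calibration, response = "mides_mm",
                        candidates = candidates)
  model <- as_fruit_model(mides_fit, response = "mides_mm")
  graded <- validation |>
    estimate_fruit(mides = model, volume = volume_model()) |>
    grade_fruit(rule = rule)
  confusion_initial <- build_confusion(graded$grade, graded$actual)
  lines <- fit_reclassifier(graded)
  graded <- reclassify_grades(graded, lines)
  confusion_final <- build_confusion(graded$grade_final, graded$actual)
  list(
    mides_fit = mides_fit,
    graded = graded,
    lines = lines,
    confusion_initial = confusion_initial,
    confusion_final = confusion_final
  )
}
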