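#' Grade every assessed fraction of a cohort
#'
#' @param courses list of [course_record()]s (or a single course).
#' @param criteria list of [criterion_spec()]s; default [default_criteria()].
#' @return List of [grade_fraction()] reports, pooled in course order over
#'   assessed fractions (the alignment [assess_categories()] expects).
#' @export
grade_courses <- function(courses, criteria = default_criteria()) {
  if (inherits(courses, "course_record")) courses <- list(courses)
  unlist(lapply(courses, function(cr) {
    lapply(assessed_indices(cr), function(i)
      grade_fraction(cr$fractions[[i]], cr$planned_parameters, criteria))
  }), recursive = FALSE)
}

#' End-to-end flag evaluation of a cohort
#'
#' Applies the flagging protocol to every course, grades each assessed
#' fraction against the violation criteria, and runs the truth-table
#' analysis per violation category. This is the package's main entry point:
#' it answers "how well does the body-contour flag identify the fractions a
#' physician would have wanted replanned?".
#'
#' @param courses list of [course_record()]s with contour changes recorded.
#' @param criteria list of [criterion_spec()]s.
#' @param protocol a [flag_protocol()].
#' @param weights optional per-assessed-fraction weights.
#' @return An [assess_categories()] result (`art_assessment`), with the
#'   graded reports attached as attribute `"reports"` and the flagged
#'   courses as attribute `"courses"`.
#' @export
art_evaluate <- function(courses, criteria = default_criteria(),
                         protocol = flag_protocol(), weights = NULL) {
  if (inherits(courses, "course_record")) courses <- list(courses)
  courses <- lapply(courses, apply_flag, protocol = protocol)
  reports <- grade_courses(courses, criteria)
  out <- assess_categories(courses, reports, weights)
  attr(out, "reports") <- reports
  attr(out, "courses") <- courses
  out
}

#' Threshold sweep over an evaluated cohort
#'
#' Convenience wrapper: re-thresholds the recorded contour changes of an
#' [art_evaluate()] result against one violation category's ground truth.
#'
#' @param evaluation an [art_evaluate()] result.
#' @param thresholds candidate thresholds in cm.
#' @param category violation category supplying ground truth.
#' @return The [threshold_sweep()] data.frame.
#' @export
sweep_evaluation <- function(evaluation, thresholds = c(0.5, 1.0, 1.5, 2.0),
                             category = "all_major") {
  courses <- attr(evaluation, "courses")
  reports <- attr(evaluation, "reports")
  stopifnot(!is.null(courses), !is.null(reports),
            category %in% names(category_labels()))
  cc <- unlist(lapply(courses, function(cr)
    vapply(cr$fractions[assessed_indices(cr)],
           function(f) f$contour_change, numeric(1))))
  viol <- vapply(reports, function(r) r$categories[[category]], logical(1))
  threshold_sweep(cc, viol, thresholds)
}
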