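#' One assessed (or unassessed) treatment fraction
#'
#' @param fraction_index 1-based fraction number.
#' @param assessed was a CBCT acquired at this fraction?
#' @param contour_change measured body-contour change in cm (max axial
#'   slice-based Hausdorff distance), or `NA` when not assessed.
#' @param flagged flag state; only an assessed fraction can be flagged.
#' @param parameters named numeric vector of dose-parameter values (Gy or
#'   % volume); present only when assessed.
#' @return Object of class `fraction_record`.
#' @export
fraction_record <- function(fraction_index, assessed = FALSE,
                            contour_change = NA_real_, flagged = FALSE,
                            parameters = NULL) {
  fraction_index <- as.integer(fraction_index)
  stopifnot(fraction_index >= 1L)
  if (!assessed) {
    if (isTRUE(flagged))
      stop("an unassessed fraction cannot be flagged", call. = FALSE)
    if (!is.null(parameters) && length(parameters))
      stop("parameters are only recorded for assessed fractions", call. = FALSE)
    contour_change <- NA_real_
  }
  if (!is.na(contour_change) && contour_change < 0)
    stop("contour_change must be >= 0 cm", call. = FALSE)
  structure(list(fraction_index = fraction_index, assessed = isTRUE(assessed),
                 contour_change = as.numeric(contour_change),
                 flagged = isTRUE(flagged),
                 parameters = parameters),
            class = "fraction_record")
}

#' One patient's treatment course
#'
#' Holds the plan, the planned (baseline) dose-parameter values, and one
#' [fraction_record()] per fraction, indices complete and unique over
#' `1..n_fractions`.
#'
#' @param patient_id identifier.
#' @param plan a [course_plan()].
#' @param planned_parameters named numeric vector of planned parameter values.
#' @param fractions list of [fraction_record()]s, one per fraction.
#' @return Object of class `course_record`.
#' @export
course_record <- function(patient_id, plan, planned_parameters, fractions) {
  stopifnot(inherits(plan, "course_plan"), is.list(fractions))
  idx <- vapply(fractions, function(f) f$fraction_index, integer(1))
  if (!identical(sort(idx), seq_len(plan$n_fractions)))
    stop(sprintf("course '%s' must have exactly fractions 1..%d",
                 patient_id, plan$n_fractions), call. = FALSE)
  structure(list(patient_id = as.character(patient_id), plan = plan,
                 planned_parameters = planned_parameters,
                 fractions = fractions[order(idx)]),
            class = "course_record")
}

#' @export
print.course_record <- function(x, ...) {
  a <- assessed_indices(x)
  f <- vapply(x$fractions, function(r) r$flagged, logical(1))
  cat(sprintf("<course_record> patient %s: %d fx, %d assessed (fx %s), %d flagged\n",
              x$patient_id, x$plan$n_fractions, length(a),
              paste(a, collapse = ","), sum(f)))
  invisible(x)
}

#' Indices of assessed fractions of a course
#' @param course a [course_record()].
#' @return Integer vector of 1-based fraction indices with CBCT assessment.
#' @export
assessed_indices <- function(course) {
  which(vapply(course$fractions, function(f) f$assessed, logical(1)))
}

# Named numeric vector of one parameter over assessed fractions.
assessed_values <- function(course, parameter) {
  idx <- assessed_indices(course)
  v <- vapply(idx, function(i) {
    p <- course$fractions[[i]]$parameters
    if (is.null(p) || !parameter %in% names(p)) NA_real_ else p[[parameter]]
  }, numeric(1))
  names(v) <- idx
  v
}
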