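#' Aggregate survey responses into violation margins
#'
#' Radiation oncologists are asked, per planning objective, what percentage
#' violation observed on a single assessed fraction would warrant a replan.
#' The per-parameter margin is the median of the responses (even counts use
#' the mean of the two middle values, the usual sample median).
#'
#' @param responses named list: parameter id -> numeric vector of percentage
#'   responses, one per respondent (each > 0).
#' @return Named numeric vector of median violation percentages.
#' @examples
#' aggregate_survey(list(cord_dmax = c(3, 3, 5, 5, 10)))  # 5
#' @export
aggregate_survey <- function(responses) {
  stopifnot(is.list(responses), !is.null(names(responses)))
  vapply(names(responses), function(p) {
    r <- responses[[p]]
    if (!length(r)) stop(sprintf("no survey responses for '%s'", p),
                         call. = FALSE)
    if (any(!is.finite(r)) || any(r <= 0))
      stop(sprintf("responses for '%s' must be finite percentages > 0", p),
           call. = FALSE)
    stats::median(r)
  }, numeric(1))
}

#' One replan violation criterion
#'
#' A criterion compares a per-fraction DVH parameter with a reference — the
#' institutional planning objective, or the planned parameter value when no
#' formal objective exists (`reference = "planned"`). Direction `"limit"`
#' flags overdose (violation when the value strictly exceeds
#' `reference * (1 + v/100)`); `"coverage"` flags underdose (violation when
#' the value falls strictly below `reference * (1 - v/100)`). The severity
#' class is a property of the criterion: target coverage and
#' brainstem/spinal-cord sparing are major-class; target hot spot and
#' parotid sparing are minor-class.
#'
#' @param parameter DVH parameter id this criterion grades.
#' @param structure structure the parameter belongs to.
#' @param reference numeric reference in Gy (or % volume), or the string
#'   `"planned"` to use the course's planned parameter value.
#' @param direction `"limit"` or `"coverage"`.
#' @param v_major major-violation margin in percent (or `NA`).
#' @param v_minor minor-violation margin in percent (or `NA`).
#' @param class `"major"` or `"minor"` severity class.
#' @return Object of class `criterion_spec`.
#' @export
criterion_spec <- function(parameter, structure, reference,
                           direction = c("limit", "coverage"),
                           v_major = NA_real_, v_minor = NA_real_,
                           class = c("major", "minor")) {
  direction <- match.arg(direction)
  class <- match.arg(class)
  if (!identical(reference, "planned")) {
    reference <- as.numeric(reference)
    if (!is.finite(reference) || reference <= 0)
      stop("`reference` must be positive (or \"planned\")", call. = FALSE)
  }
  if (!is.na(v_major) && !is.na(v_minor) && v_major < v_minor)
    stop("v_major must be >= v_minor when both are given", call. = FALSE)
  structure(list(parameter = parameter, structure = structure,
                 reference = reference, direction = direction,
                 v_major = as.numeric(v_major), v_minor = as.numeric(v_minor),
                 class = class),
            class = "criterion_spec")
}

resolve_reference <- function(criterion, planned = NULL) {
  if (!identical(criterion$reference, "planned")) return(criterion$reference)
  if (is.null(planned) || !criterion$parameter %in% names(planned))
    stop(sprintf("criterion '%s' uses the planned value but none was supplied",
                 criterion$parameter), call. = FALSE)
  planned[[criterion$parameter]]
}

#' Threshold value of a criterion at a given severity
#'
#' `limit` direction: `reference * (1 + v/100)`; `coverage` direction:
#' `reference * (1 - v/100)`. The spinal-cord major threshold, 48 Gy + 3%,
#' reports as 49.4 Gy at the usual 0.1 Gy precision.
#'
#' @param criterion a [criterion_spec()].
#' @param severity `"major"` or `"minor"`.
#' @param planned named numeric vector of planned values, needed when the
#'   criterion's reference is `"planned"`.
#' @return Threshold in the parameter's units.
#' @examples
#' cs <- criterion_spec("cord_dmax", "spinal_cord", 48, "limit", v_major = 3)
#' round(violation_threshold(cs, "major"), 1)  # 49.4
#' @export
violation_threshold <- function(criterion, severity = c("major", "minor"),
                                planned = NULL) {
  severity <- match.arg(severity)
  v <- if (severity == "major") criterion$v_major else criterion$v_minor
  if (is.na(v))
    stop(sprintf("criterion '%s' has no %s margin", criterion$parameter,
                 severity), call. = FALSE)
  ref <- resolve_reference(criterion, planned)
  if (criterion$direction == "limit") ref * (1 + v / 100)
  else ref * (1 - v / 100)
}

breaches <- function(value, criterion, severity, planned) {
  th <- violation_threshold(criterion, severity, planned)
  if (criterion$direction == "limit") value > th else value < th
}

structure_group <- function(structure) {
  if (grepl("^ptv", structure)) "ptv"
  else if (grepl("^(gtv|ctv)", structure)) "target_core"
  else if (grepl("spinal_cord|brainstem|optic", structure)) "oar"
  else "other"
}

#' Grade one assessed fraction against the violation criteria
#'
#' Each criterion's parameter value is compared with its major and minor
#' thresholds (strict breach beyond the threshold; a value exactly at a
#' threshold is not a violation). The per-parameter status is `"major"`,
#' `"minor"` or `"none"`, and the truth-table category memberships are
#' derived from the major statuses: all major violations; all major
#' excluding PTV parameters; organs at risk (brainstem, spinal cord,
#' optics); target coverage including PTV (GTV, CTV, PTV); and target
#' coverage excluding PTV (GTV, CTV).
#'
#' @param record a [fraction_record()] with extracted parameters, or a named
#'   numeric vector of parameter values.
#' @param planned named numeric vector of planned parameter values.
#' @param criteria list of [criterion_spec()]s; every criterion's parameter
#'   must be present.
#' @return Object of class `violation_report` with `fraction_index`,
#'   `status` (named character) and `categories` (named logical).
#' @export
grade_fraction <- function(record, planned, criteria) {
  if (inherits(record, "fraction_record")) {
    values <- record$parameters
    fx <- record$fraction_index
  } else {
    values <- record
    fx <- NA_integer_
  }
  status <- vapply(criteria, function(cr) {
    if (!cr$parameter %in% names(values))
      stop(sprintf("parameter '%s' required by the criteria is missing",
                   cr$parameter), call. = FALSE)
    v <- values[[cr$parameter]]
    if (!is.na(cr$v_major) && breaches(v, cr, "major", planned)) "major"
    else if (!is.na(cr$v_minor) && breaches(v, cr, "minor", planned)) "minor"
    else "none"
  }, character(1))
  names(status) <- vapply(criteria, function(cr) cr$parameter, character(1))
  grp <- vapply(criteria, function(cr) structure_group(cr$structure),
                character(1))
  major <- status == "major"
  categories <- c(
    all_major = any(major),
    all_major_excl_ptv = any(major & grp != "ptv"),
    oar = any(major & grp == "oar"),
    target_with_ptv = any(major & grp %in% c("ptv", "target_core")),
    target_without_ptv = any(major & grp == "target_core")
  )
  structure(list(fraction_index = fx, status = status,
                 categories = categories),
            class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  nmaj <- sum(x$status == "major"); nmin <- sum(x$status == "minor")
  cat(sprintf("<violation_report> fx %s: %d major, %d minor violation(s)\n",
              ifelse(is.na(x$fraction_index), "?", x$fraction_index),
              nmaj, nmin))
  invisible(x)
}

#' Default (reconstructed) violation criteria
#'
#' The institutional criteria table is not fully recoverable; this default
#' set is a reconstruction anchored on the values that are: the spinal-cord
#' Dmax objective of 48 Gy with a 3% major overdose margin (threshold
#' 49.4 Gy), GTV/CTV criteria copied from the PTV criteria (no formal
#' objectives exist for them), target coverage and brainstem/cord sparing as
#' major-class, target hot spot and parotid sparing as minor-class. Percent
#' margins without a printed value (target coverage 5%, hot spot 5%,
#' parotid 10%) are package defaults; see the shipped
#' `extdata/default_criteria.yaml` and the methods vignette.
#'
#' @param include_parotids include the minor-class parotid Dmean criteria.
#' @return List of [criterion_spec()]s.
#' @export
default_criteria <- function(include_parotids = TRUE) {
  cr <- list(
    criterion_spec("cord_dmax", "spinal_cord", 48, "limit",
                   v_major = 3, class = "major"),
    criterion_spec("brainstem_dmax", "brainstem", 54, "limit",
                   v_major = 3, class = "major"),
    criterion_spec("gtv_high_d99", "gtv_high", "planned", "coverage",
                   v_major = 5, class = "major"),
    criterion_spec("ctv_high_d99", "ctv_high", "planned", "coverage",
                   v_major = 5, class = "major"),
    criterion_spec("ctv_low_d99", "ctv_low", "planned", "coverage",
                   v_major = 5, class = "major"),
    criterion_spec("ptv_high_d95", "ptv_high", "planned", "coverage",
                   v_major = 5, class = "major"),
    criterion_spec("ptv_low_d95", "ptv_low", "planned", "coverage",
                   v_major = 5, class = "major"),
    criterion_spec("ptv_high_dmax", "ptv_high", "planned", "limit",
                   v_minor = 5, class = "minor")
  )
  if (include_parotids) {
    cr <- c(cr, list(
      criterion_spec("parotid_left_dmean", "parotid_left", "planned", "limit",
                     v_minor = 10, class = "minor"),
      criterion_spec("parotid_right_dmean", "parotid_right", "planned",
                     "limit", v_minor = 10, class = "minor")
    ))
  }
  cr
}

#' Read / write a criteria configuration file
#'
#' YAML schema: a list under `criteria`, each entry with fields `parameter`,
#' `structure`, `reference` (number or `"planned"`), `direction`, `v_major`,
#' `v_minor`, `class`.
#'
#' @param path file path.
#' @return `read_criteria`: list of [criterion_spec()]s.
#' @export
read_criteria <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$criteria))
    stop("criteria file must contain a top-level `criteria` list",
         call. = FALSE)
  lapply(cfg$criteria, function(e)
    criterion_spec(e$parameter, e$structure, e$reference,
                   e$direction %||% "limit",
                   v_major = e$v_major %||% NA_real_,
                   v_minor = e$v_minor %||% NA_real_,
                   class = e$class %||% "major"))
}

#' @param criteria list of [criterion_spec()]s.
#' @rdname read_criteria
#' @export
write_criteria <- function(criteria, path) {
  entries <- lapply(criteria, function(cr) {
    e <- list(parameter = cr$parameter, structure = cr$structure,
              reference = cr$reference, direction = cr$direction,
              class = cr$class)
    if (!is.na(cr$v_major)) e$v_major <- cr$v_major
    if (!is.na(cr$v_minor)) e$v_minor <- cr$v_minor
    e
  })
  yaml::write_yaml(list(criteria = entries), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
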