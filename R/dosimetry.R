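#' Specification of one DVH parameter
#'
#' Identifies a structure and a cumulative-DVH statistic: `Dmax` (hottest
#' voxel), `Dmean`, `Dx%` (largest dose received by at least x% of the
#' structure volume; the k-th highest voxel dose with k = ceiling(x/100 * N),
#' no fractional interpolation) or `VxGy` (percent of the structure volume
#' receiving at least x Gy; inclusive comparison).
#'
#' @param id parameter identifier, e.g. `"cord_dmax"`, `"ptv_high_d95"`.
#' @param structure structure name in the [structure_set()].
#' @param kind one of `"max"`, `"mean"`, `"dose_at_volume"`, `"volume_at_dose"`.
#' @param level volume percent in (0, 100] for `dose_at_volume`; dose level
#'   in Gy (> 0) for `volume_at_dose`; ignored otherwise.
#' @param exclude optional structure name whose voxels are subtracted from
#'   the mask before evaluation (the low-dose PTV is evaluated excluding the
#'   high-dose PTV volume).
#' @return Object of class `dose_parameter_spec`.
#' @export
dose_parameter_spec <- function(id, structure,
                                kind = c("max", "mean", "dose_at_volume",
                                         "volume_at_dose"),
                                level = NA_real_, exclude = NULL) {
  kind <- match.arg(kind)
  if (kind == "dose_at_volume" &&
      (is.na(level) || level <= 0 || level > 100))
    stop("dose_at_volume requires a volume percent in (0, 100]", call. = FALSE)
  if (kind == "volume_at_dose" && (is.na(level) || level <= 0))
    stop("volume_at_dose requires a dose level > 0 Gy", call. = FALSE)
  structure(list(id = id, structure = structure, kind = kind,
                 level = as.numeric(level), exclude = exclude),
            class = "dose_parameter_spec")
}

#' Evaluate one DVH parameter on a dose grid
#'
#' @param dose numeric array of absorbed dose in Gy, same shape as `mask`.
#' @param mask logical structure mask, non-empty.
#' @param spec a [dose_parameter_spec()].
#' @return The parameter value: Gy for dose statistics, percent of structure
#'   volume for `volume_at_dose`.
#' @export
dvh_parameter <- function(dose, mask, spec) {
  stopifnot(inherits(spec, "dose_parameter_spec"))
  if (!identical(dim(dose), dim(mask)))
    stop("dose and mask must share one grid", call. = FALSE)
  v <- dose[mask]
  if (!length(v))
    stop(sprintf("structure '%s' is empty: cannot evaluate '%s'",
                 spec$structure, spec$id), call. = FALSE)
  switch(spec$kind,
    max = max(v),
    mean = mean(v),
    dose_at_volume = {
      k <- ceiling(spec$level / 100 * length(v))
      sort(v, decreasing = TRUE)[k]
    },
    volume_at_dose = 100 * sum(v >= spec$level) / length(v)
  )
}

# Resolve a spec's mask from a structure set, applying any exclusion.
resolve_mask <- function(structures, spec) {
  m <- structures$masks[[spec$structure]]
  if (is.null(m))
    stop(sprintf("structure '%s' required by parameter '%s' is missing",
                 spec$structure, spec$id), call. = FALSE)
  if (!is.null(spec$exclude)) {
    ex <- structures$masks[[spec$exclude]]
    if (!is.null(ex)) m <- m & !ex
  }
  m
}

#' Evaluate all DVH parameters for one assessed fraction
#'
#' @param dose numeric dose array in Gy on the structure set's grid.
#' @param structures a [structure_set()] for the assessed fraction.
#' @param specs list of [dose_parameter_spec()]s.
#' @return Named numeric vector of parameter values (possibly empty).
#' @export
extract_fraction_parameters <- function(dose, structures, specs) {
  stopifnot(inherits(structures, "structure_set"))
  out <- vapply(specs, function(s)
    dvh_parameter(dose, resolve_mask(structures, s), s), numeric(1))
  names(out) <- vapply(specs, function(s) s$id, character(1))
  out
}

#' Full-course parameter series by linear interpolation
#'
#' Fractions without CBCT assessment receive linearly interpolated values
#' between the neighbouring assessed fractions; before the first and after
#' the last assessed fraction the nearest assessed value is held constant.
#' The accumulated estimate is the arithmetic mean of the per-fraction
#' values over the whole course (e.g. averaged over 33 fractions).
#'
#' @param fractions integer vector of assessed fraction indices (1-based).
#' @param values numeric vector of parameter values at those fractions.
#' @param n_fractions total number of fractions.
#' @param id parameter identifier carried through to the result.
#' @return Object of class `parameter_series` with `values` (length
#'   `n_fractions`), `assessed` (indices) and `accumulated` (mean).
#' @export
interpolate_series <- function(fractions, values, n_fractions = 33L,
                               id = NULL) {
  stopifnot(length(fractions) == length(values))
  keep <- !is.na(values)
  fractions <- as.integer(fractions[keep]); values <- values[keep]
  if (!length(fractions))
    stop("at least one assessed (fraction, value) pair is required",
         call. = FALSE)
  if (any(fractions < 1L | fractions > n_fractions))
    stop("assessed fraction indices must lie in 1..n_fractions", call. = FALSE)
  full <- if (length(fractions) == 1L) rep(values, n_fractions) else
    stats::approx(fractions, values, xout = seq_len(n_fractions),
                  method = "linear", rule = 2)$y
  structure(list(id = id, values = full, assessed = fractions,
                 accumulated = mean(full)),
            class = "parameter_series")
}

#' @export
print.parameter_series <- function(x, ...) {
  cat(sprintf("<parameter_series>%s %d fx (%d assessed), accumulated %.3f\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$values), length(x$assessed), x$accumulated))
  invisible(x)
}

#' Accumulate every parameter of a course
#'
#' Applies [interpolate_series()] to each parameter recorded on the assessed
#' fractions of a course.
#'
#' @param course a [course_record()] with extracted parameters.
#' @return Named list of [interpolate_series()] results, one per parameter.
#' @export
accumulate_course <- function(course) {
  stopifnot(inherits(course, "course_record"))
  idx <- assessed_indices(course)
  if (!length(idx)) stop("course has no assessed fractions", call. = FALSE)
  params <- unique(unlist(lapply(idx, function(i)
    names(course$fractions[[i]]$parameters))))
  out <- lapply(params, function(p) {
    v <- assessed_values(course, p)
    interpolate_series(as.integer(names(v)), v,
                       n_fractions = course$plan$n_fractions, id = p)
  })
  names(out) <- params
  out
}
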