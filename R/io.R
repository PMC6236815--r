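# CSV/JSON interchange. The course CSV carries one row per (patient,
# fraction) plus a fraction-0 row per patient holding the planned parameter
# values; a schema-version comment line heads every file so readers can
# reject unknown layouts loudly.

course_csv_version <- 1L

csv_header_line <- function(seed = NULL, config = NULL) {
  h <- sprintf("# artflag course csv schema_version=%d", course_csv_version)
  if (!is.null(seed)) h <- paste0(h, " seed=", seed)
  if (!is.null(config)) h <- paste0(h, " config_hash=", config_hash(config))
  h
}

#' Hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; embedded in output headers so a
#' run can be traced to its configuration.
#'
#' @param config any serializable R object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Write / read a cohort course CSV
#'
#' Columns: `patient_id`, `fraction` (0 = planned values), `assessed`,
#' `contour_change_cm`, `flagged`, then one column per DVH parameter id.
#' Reading validates the schema version, rejects flags on unassessed
#' fractions and missing assessed-fraction parameters (with row numbers).
#'
#' @param courses list of [course_record()]s.
#' @param path file path.
#' @param seed,config optional provenance recorded in the header line.
#' @return `read_course_csv`: list of [course_record()]s.
#' @export
write_course_csv <- function(courses, path, seed = NULL, config = NULL) {
  if (inherits(courses, "course_record")) courses <- list(courses)
  params <- unique(unlist(lapply(courses, function(cr)
    c(names(cr$planned_parameters),
      unlist(lapply(cr$fractions, function(f) names(f$parameters)))))))
  rows <- list()
  for (cr in courses) {
    base <- data.frame(patient_id = cr$patient_id, fraction = 0L,
                       assessed = FALSE, contour_change_cm = NA_real_,
                       flagged = FALSE)
    for (p in params) base[[p]] <- cr$planned_parameters[[p]] %||% NA_real_
    rows[[length(rows) + 1L]] <- base
    for (f in cr$fractions) {
      r <- data.frame(patient_id = cr$patient_id, fraction = f$fraction_index,
                      assessed = f$assessed,
                      contour_change_cm = round(f$contour_change, 6),
                      flagged = f$flagged)
      for (p in params)
        r[[p]] <- if (f$assessed) round(f$parameters[[p]] %||% NA_real_, 6)
                  else NA_real_
      rows[[length(rows) + 1L]] <- r
    }
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header_line(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_course_csv
#' @export
read_course_csv <- function(path) {
  if (!file.exists(path))
    stop("course CSV not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 1L)
  if (!length(lines) || !nzchar(lines))
    stop("empty course CSV: ", path, call. = FALSE)
  if (!grepl("^# artflag course csv", lines))
    stop("not an artflag course CSV (missing schema header): ", path,
         call. = FALSE)
  ver <- sub(".*schema_version=(\\d+).*", "\\1", lines)
  if (as.integer(ver) != course_csv_version)
    stop(sprintf("unsupported course CSV schema version %s (reader supports %d)",
                 ver, course_csv_version), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  if (!nrow(df)) stop("course CSV has no data rows: ", path, call. = FALSE)
  fixed <- c("patient_id", "fraction", "assessed", "contour_change_cm",
             "flagged")
  miss <- setdiff(fixed, names(df))
  if (length(miss))
    stop("course CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  params <- setdiff(names(df), fixed)
  bad <- which(df$flagged & !df$assessed & df$fraction > 0)
  if (length(bad))
    stop("flagged=TRUE on unassessed fraction(s) at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (length(params)) {
    amiss <- which(df$assessed & df$fraction > 0 &
                     apply(is.na(df[params]), 1, any))
    if (length(amiss))
      stop("assessed fraction(s) with missing parameter values at row(s): ",
           paste(amiss, collapse = ", "), call. = FALSE)
  }
  lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$fraction), ]
    planned <- d[d$fraction == 0L, params, drop = FALSE]
    planned_v <- if (nrow(planned)) unlist(planned[1, ]) else NULL
    dd <- d[d$fraction > 0L, , drop = FALSE]
    plan <- course_plan(n_fractions = max(dd$fraction))
    fractions <- lapply(seq_len(nrow(dd)), function(i) {
      r <- dd[i, ]
      fraction_record(r$fraction, assessed = r$assessed,
                      contour_change = r$contour_change_cm,
                      flagged = r$flagged,
                      parameters = if (r$assessed)
                        unlist(r[params]) else NULL)
    })
    course_record(d$patient_id[1], plan, planned_v, fractions)
  })
}

#' Write the truth-table and diagnostic-metric report CSVs
#'
#' `table` style: one row per violation category with TP/FN/FP/TN counts
#' and percent-of-total columns; `metrics` style: one row per category with
#' the five diagnostic statistics in percent (one decimal), absent
#' (zero-denominator) values left empty.
#'
#' @param assessment an [assess_categories()] result.
#' @param counts_path,metrics_path output file paths (`NULL` to skip one).
#' @param seed,config optional provenance recorded in a header line.
#' @return Invisibly, the written paths.
#' @export
write_assessment_csv <- function(assessment, counts_path = NULL,
                                 metrics_path = NULL, seed = NULL,
                                 config = NULL) {
  stopifnot(inherits(assessment, "art_assessment"))
  hdr <- sub("course csv schema_version=1", "report csv",
             csv_header_line(seed, config), fixed = TRUE)
  emit <- function(df, path) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  if (!is.null(counts_path)) {
    df <- assessment$counts
    for (col in c("TP_pct", "FN_pct", "FP_pct", "TN_pct"))
      df[[col]] <- round(df[[col]], 1)
    emit(df, counts_path)
  }
  if (!is.null(metrics_path)) {
    m <- summary(assessment)$metrics
    for (col in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
      m[[col]] <- round(100 * m[[col]], 1)
    emit(m, metrics_path)
  }
  invisible(c(counts_path, metrics_path))
}

#' Write a run manifest
#'
#' JSON record of the configuration, its hash, the seed and the package
#' version, so any output directory is self-describing.
#'
#' @param path output path.
#' @param config configuration list.
#' @param seed RNG seed of the run.
#' @return Invisibly, the path.
#' @export
write_run_manifest <- function(path, config = list(), seed = NULL) {
  manifest <- list(
    package = "artflag",
    version = as.character(utils::packageVersion("artflag")),
    seed = seed,
    config_hash = config_hash(config),
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read a survey response CSV
#'
#' Respondent-by-parameter grid: first column `respondent`, remaining
#' columns one per parameter id, cells the percentage-violation responses.
#'
#' @param path file path.
#' @return Named list suitable for [aggregate_survey()].
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"respondent" %in% names(df))
    stop("survey CSV must have a `respondent` column", call. = FALSE)
  cols <- setdiff(names(df), "respondent")
  out <- lapply(cols, function(p) df[[p]][!is.na(df[[p]])])
  names(out) <- cols
  out
}
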