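#' Truth table of flag state against violation state
#'
#' Each assessed fraction is considered independently. TP: flagged with a
#' clinically significant deviation; FN: unflagged with a deviation; FP:
#' flagged without; TN: neither.
#'
#' @param flags logical vector, one element per assessed fraction.
#' @param violations logical vector, aligned with `flags`.
#' @param category label carried into reports.
#' @return Object of class `truth_table` with counts TP, FN, FP, TN and
#'   `total`.
#' @export
truth_table <- function(flags, violations, category = "all") {
  if (length(flags) != length(violations))
    stop("flags and violations must have equal length", call. = FALSE)
  flags <- as.logical(flags); violations <- as.logical(violations)
  structure(list(
    category = category,
    TP = sum(flags & violations),
    FN = sum(!flags & violations),
    FP = sum(flags & !violations),
    TN = sum(!flags & !violations),
    total = length(flags)
  ), class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> %s: TP %d, FN %d, FP %d, TN %d (n = %d)\n",
              x$category, x$TP, x$FN, x$FP, x$TN, x$total))
  invisible(x)
}

#' The five diagnostic accuracy statistics of a truth table
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), positive predictive
#' value = TP/(TP+FP), negative predictive value = TN/(TN+FN), accuracy =
#' (TP+TN)/total. A ratio with a zero denominator is reported as `NA`
#' (absent), never as 0.
#'
#' @param t a [truth_table()].
#' @return Object of class `diagnostic_metrics`; proportions in \[0, 1\].
#' @export
diagnostic_metrics <- function(t) {
  stopifnot(inherits(t, "truth_table"))
  if (t$total == 0) stop("truth table is empty", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    category = t$category,
    sensitivity = ratio(t$TP, t$TP + t$FN),
    specificity = ratio(t$TN, t$TN + t$FP),
    ppv = ratio(t$TP, t$TP + t$FP),
    npv = ratio(t$TN, t$TN + t$FN),
    accuracy = (t$TP + t$TN) / t$total
  ), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  pc <- function(v) if (is.na(v)) "--" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("<diagnostic_metrics> %s: sens %s, spec %s, ppv %s, npv %s, acc %s\n",
              x$category, pc(x$sensitivity), pc(x$specificity), pc(x$ppv),
              pc(x$npv), pc(x$accuracy)))
  invisible(x)
}

category_labels <- function() {
  c(all_major = "All major violations",
    all_major_excl_ptv = "All major violations excluding PTV",
    oar = "Organs at risk (brainstem, spinal cord, optics)",
    target_with_ptv = "Target coverage (GTV, CTV, PTV)",
    target_without_ptv = "Target coverage (GTV, CTV)")
}

#' Truth-table analysis per violation category
#'
#' Pools the assessed fractions of all courses, cross-tabulating the
#' protocol's flag states against each category's violation states, and
#' computes the five diagnostic metrics per category. Optional per-fraction
#' weights (defaulting to uniform) allow, e.g., weighting flagging accuracy
#' more heavily during the first half of treatment; weighted counts are
#' reported alongside the raw ones when weights are non-uniform.
#'
#' @param courses list of [course_record()]s with flags applied.
#' @param reports list (aligned with the pooled assessed fractions, in
#'   course order) of [grade_fraction()] results.
#' @param weights optional numeric vector of per-assessed-fraction weights.
#' @return Object of class `art_assessment`: a list with `tables` (truth
#'   tables), `metrics`, `counts` data.frame (category, TP/FN/FP/TN with
#'   percent of total) and `n` (assessed fractions pooled).
#' @export
assess_categories <- function(courses, reports, weights = NULL) {
  if (inherits(courses, "course_record")) courses <- list(courses)
  flags <- unlist(lapply(courses, function(cr)
    vapply(cr$fractions[assessed_indices(cr)], function(f) f$flagged,
           logical(1))))
  n <- length(flags)
  if (length(reports) != n)
    stop(sprintf("got %d violation reports for %d assessed fractions",
                 length(reports), n), call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  cats <- names(category_labels())
  tables <- lapply(cats, function(cat) {
    viol <- vapply(reports, function(r) r$categories[[cat]], logical(1))
    truth_table(flags, viol, category = cat)
  })
  names(tables) <- cats
  metrics <- lapply(tables, diagnostic_metrics)
  counts <- do.call(rbind, lapply(cats, function(cat) {
    t <- tables[[cat]]
    data.frame(category = category_labels()[[cat]], TP = t$TP, FN = t$FN,
               FP = t$FP, TN = t$TN,
               TP_pct = 100 * t$TP / t$total, FN_pct = 100 * t$FN / t$total,
               FP_pct = 100 * t$FP / t$total, TN_pct = 100 * t$TN / t$total,
               row.names = NULL)
  }))
  structure(list(tables = tables, metrics = metrics, counts = counts,
                 n = n, weights = weights),
            class = "art_assessment")
}

#' @export
print.art_assessment <- function(x, ...) {
  cat(sprintf("ART flag assessment over %d assessed fractions\n\n", x$n))
  df <- x$counts
  df$TP <- sprintf("%d (%.0f%%)", df$TP, df$TP_pct)
  df$FN <- sprintf("%d (%.0f%%)", df$FN, df$FN_pct)
  df$FP <- sprintf("%d (%.0f%%)", df$FP, df$FP_pct)
  df$TN <- sprintf("%d (%.0f%%)", df$TN, df$TN_pct)
  print(df[, c("category", "TP", "FN", "FP", "TN")], right = FALSE)
  invisible(x)
}

#' @export
summary.art_assessment <- function(object, ...) {
  m <- do.call(rbind, lapply(object$metrics, function(mm)
    data.frame(category = category_labels()[[mm$category]],
               sensitivity = mm$sensitivity, specificity = mm$specificity,
               ppv = mm$ppv, npv = mm$npv, accuracy = mm$accuracy,
               row.names = NULL)))
  structure(list(metrics = m, n = object$n),
            class = "summary.art_assessment")
}

#' @export
print.summary.art_assessment <- function(x, ...) {
  cat(sprintf("Diagnostic metrics per violation category (n = %d fractions)\n",
              x$n))
  m <- x$metrics
  for (col in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    m[[col]] <- ifelse(is.na(m[[col]]), "--",
                       sprintf("%.1f%%", 100 * m[[col]]))
  print(m, right = FALSE)
  invisible(x)
}

#' @export
plot.art_assessment <- function(x, ...) {
  m <- summary(x)$metrics
  vals <- t(as.matrix(m[, c("sensitivity", "specificity", "ppv", "npv",
                            "accuracy")])) * 100
  colnames(vals) <- abbreviate(m$category, 18)
  graphics::barplot(vals, beside = TRUE, ylim = c(0, 100),
                    ylab = "percent", las = 2,
                    legend.text = rownames(vals),
                    args.legend = list(x = "topright", cex = 0.7), ...)
  invisible(x)
}

#' Random-flag sensitivity baseline
#'
#' Reconstruction of the random-sample comparison: each of `k` assessed
#' fractions per patient is flagged independently with probability `p_flag`
#' and carries a clinically significant deviation independently with
#' probability `p_viol`. When `condition_on_flagged` is TRUE, patients with
#' zero flagged fractions are excluded before pooling the per-patient truth
#' tables — emulating a study cohort restricted to flagged patients — and
#' the pooled sensitivity has closed form `p_flag / (1 - (1 - p_flag)^k)`,
#' independent of `p_viol`. Without conditioning the closed form is simply
#' `p_flag`. At the defaults (p_flag 0.20, p_viol 0.15, k = 6) the
#' conditioned closed form is 0.271, i.e. 27% sensitivity.
#'
#' @param p_flag per-fraction flag probability.
#' @param p_viol per-fraction violation probability.
#' @param k assessed fractions per patient.
#' @param n_patients number of Monte-Carlo patients.
#' @param condition_on_flagged retain only patients with at least one flag.
#' @param seed optional RNG seed (local to this call).
#' @return List with `closed_form`, `mc_estimate`, `mc_se` (binomial
#'   standard error of the pooled estimate), `table` (the pooled
#'   [truth_table()]), `n_retained`, and the model parameters.
#' @export
random_flag_sensitivity <- function(p_flag = 0.20, p_viol = 0.15, k = 6L,
                                    n_patients = 100000L,
                                    condition_on_flagged = TRUE,
                                    seed = NULL) {
  stopifnot(p_flag >= 0, p_flag <= 1, p_viol >= 0, p_viol <= 1, k >= 1)
  if (condition_on_flagged && p_flag == 0)
    stop("p_flag = 0 with conditioning retains no patients", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  flags <- matrix(stats::runif(k * n_patients) < p_flag, nrow = k)
  viols <- matrix(stats::runif(k * n_patients) < p_viol, nrow = k)
  keep <- if (condition_on_flagged) colSums(flags) > 0 else
    rep(TRUE, n_patients)
  if (!any(keep))
    stop("no patients retained after conditioning on >= 1 flag",
         call. = FALSE)
  tt <- truth_table(as.vector(flags[, keep]), as.vector(viols[, keep]),
                    category = "random_flag_baseline")
  m <- diagnostic_metrics(tt)
  closed <- if (condition_on_flagged) p_flag / (1 - (1 - p_flag)^k) else p_flag
  npos <- tt$TP + tt$FN
  list(closed_form = closed,
       mc_estimate = m$sensitivity,
       mc_se = if (npos > 0) sqrt(m$sensitivity * (1 - m$sensitivity) / npos)
               else NA_real_,
       table = tt,
       n_retained = sum(keep),
       p_flag = p_flag, p_viol = p_viol, k = k, n_patients = n_patients,
       condition_on_flagged = condition_on_flagged, seed = seed)
}
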