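#' Body-contour flagging protocol
#'
#' The institutional ART flag: an assessed fraction is flagged when the
#' change in external body contour, measured as the maximum axial
#' slice-based Hausdorff distance between the current and planning external
#' contours, strictly exceeds the threshold (default 1.5 cm; "exceeding"
#' means a value of exactly 1.5 cm is not flagged).
#'
#' @param threshold cm, default 1.5, must be positive.
#' @param directed use the directed (current -> reference) distance instead
#'   of the symmetric Hausdorff distance; default FALSE (symmetric).
#' @return Object of class `flag_protocol`.
#' @export
flag_protocol <- function(threshold = 1.5, directed = FALSE) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  structure(list(threshold = threshold, directed = isTRUE(directed)),
            class = "flag_protocol")
}

#' Hausdorff distance between two planar point sets
#'
#' Symmetric Hausdorff distance between point sets sampled from the external
#' contour on one axial slice: the larger of the two directed distances,
#' where directed(A -> B) = max over a in A of the distance from a to its
#' nearest point of B.
#'
#' @param a,b numeric matrices with two columns (x, y in cm), non-empty.
#' @param directed if TRUE return only directed(a -> b).
#' @return Distance in cm (`>= 0`; 0 iff the sampled sets coincide, for the
#'   symmetric form).
#' @export
slice_hausdorff <- function(a, b, directed = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b))
    stop("empty contour point set: both slices must have boundary points",
         call. = FALSE)
  if (ncol(a) != 2L || ncol(b) != 2L)
    stop("contour points must be n x 2 matrices (x, y in cm)", call. = FALSE)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  rmin <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
  if (directed) return(sqrt(max(rmin)))
  t2 <- t(d2)
  cmin <- t2[cbind(seq_len(nrow(t2)), max.col(-t2, ties.method = "first"))]
  sqrt(max(max(rmin), max(cmin)))
}

# Boundary voxel centers of one mask slice: mask voxels with a non-mask
# 4-neighbor (or on the array edge). Returns an n x 2 matrix of (x, y) cm.
slice_boundary_points <- function(slice, xc, yc) {
  if (!any(slice)) return(matrix(numeric(0), ncol = 2))
  n <- dim(slice)
  pad <- matrix(FALSE, n[1] + 2L, n[2] + 2L)
  pad[2:(n[1] + 1L), 2:(n[2] + 1L)] <- slice
  interior <- pad[1:n[1], 2:(n[2] + 1L)] & pad[3:(n[1] + 2L), 2:(n[2] + 1L)] &
    pad[2:(n[1] + 1L), 1:n[2]] & pad[2:(n[1] + 1L), 3:(n[2] + 2L)]
  idx <- which(slice & !interior, arr.ind = TRUE)
  cbind(xc[idx[, 1]], yc[idx[, 2]])
}

#' Per-fraction body-contour change
#'
#' Extracts boundary point sets of the external mask on every axial slice
#' where both the reference (planning) and current contours are non-empty —
#' emulating the limited CBCT field of view — computes the slice Hausdorff
#' distance on each, and returns the per-slice values and their maximum.
#'
#' @param reference,current [structure_set()]s (or bare external masks) on
#'   the same grid, already aligned on bony anatomy.
#' @param z_range optional `c(zmin, zmax)` in cm restricting the slices
#'   compared (CBCT field-of-view crop).
#' @param directed use the directed current -> reference distance.
#' @return Object of class `contour_change_result` with elements
#'   `per_slice_distance` (named by slice index, cm), `max_distance` (cm)
#'   and `argmax_slice`.
#' @export
body_contour_change <- function(reference, current, z_range = NULL,
                                directed = FALSE) {
  ext <- function(s) if (inherits(s, "structure_set")) s$masks$external else s
  grid <- if (inherits(reference, "structure_set")) reference$grid else
    attr(reference, "grid")
  if (!is_voxel_grid(grid))
    stop("reference must be a structure_set (or carry a 'grid' attribute)",
         call. = FALSE)
  ref <- ext(reference); cur <- ext(current)
  check_mask(ref, grid, "reference external")
  check_mask(cur, grid, "current external")
  xc <- grid_centers(grid, 1); yc <- grid_centers(grid, 2)
  zc <- grid_centers(grid, 3)
  slices <- seq_len(grid$shape[3])
  if (!is.null(z_range))
    slices <- slices[zc >= z_range[1] & zc <= z_range[2]]
  d <- numeric(0)
  for (k in slices) {
    if (!any(ref[, , k]) || !any(cur[, , k])) next
    pa <- slice_boundary_points(cur[, , k], xc, yc)
    pb <- slice_boundary_points(ref[, , k], xc, yc)
    d[as.character(k)] <- slice_hausdorff(pa, pb, directed = directed)
  }
  if (!length(d))
    stop("no axial slice has a non-empty external contour in both images",
         call. = FALSE)
  structure(list(per_slice_distance = d, max_distance = max(d),
                 argmax_slice = as.integer(names(d)[which.max(d)])),
            class = "contour_change_result")
}

#' @export
print.contour_change_result <- function(x, ...) {
  cat(sprintf("<contour_change> max %.2f cm at slice %d (%d slices compared)\n",
              x$max_distance, x$argmax_slice, length(x$per_slice_distance)))
  invisible(x)
}

#' Apply the flagging protocol to a course
#'
#' Sets `flagged = contour_change > threshold` on every assessed fraction
#' with a recorded contour change; unassessed fractions are never flagged.
#'
#' @param course a [course_record()].
#' @param protocol a [flag_protocol()].
#' @return The course with updated flag states.
#' @export
apply_flag <- function(course, protocol = flag_protocol()) {
  stopifnot(inherits(course, "course_record"),
            inherits(protocol, "flag_protocol"))
  course$fractions <- lapply(course$fractions, function(f) {
    f$flagged <- f$assessed && !is.na(f$contour_change) &&
      f$contour_change > protocol$threshold
    f
  })
  course
}

#' Diagnostic metrics as a function of the flagging threshold
#'
#' Re-thresholds the recorded contour changes of the assessed fractions at
#' each candidate threshold and cross-tabulates against the supplied
#' ground-truth violation states, giving one truth table and metric set per
#' threshold (a discrete receiver-operating sweep). Sensitivity is
#' non-increasing and specificity non-decreasing in the threshold.
#'
#' @param contour_changes numeric vector, one value per assessed fraction (cm).
#' @param violations logical vector, aligned, TRUE when the fraction has a
#'   clinically significant (e.g. major) violation.
#' @param thresholds numeric vector of thresholds in cm, non-empty.
#' @return `data.frame` with one row per threshold: TP/FN/FP/TN counts and
#'   the five diagnostic metrics (proportions in \[0, 1\], `NA` when a
#'   denominator is zero).
#' @export
threshold_sweep <- function(contour_changes, violations, thresholds) {
  stopifnot(length(thresholds) >= 1L,
            length(contour_changes) == length(violations))
  rows <- lapply(thresholds, function(th) {
    tt <- truth_table(contour_changes > th, violations,
                      category = sprintf("threshold_%g", th))
    m <- diagnostic_metrics(tt)
    data.frame(threshold_cm = th, TP = tt$TP, FN = tt$FN, FP = tt$FP,
               TN = tt$TN, sensitivity = m$sensitivity,
               specificity = m$specificity, ppv = m$ppv, npv = m$npv,
               accuracy = m$accuracy)
  })
  do.call(rbind, rows)
}
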