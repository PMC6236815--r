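#' Course prescription arithmetic
#'
#' The default regimen is the radical head-and-neck schedule: 70 Gy in 33
#' fractions (2.12 Gy/fraction) to the high-risk PTV with 59.4 Gy
#' (1.8 Gy/fraction) to the low-risk PTV including prophylactic nodal
#' coverage. Dose per fraction is always prescription / n_fractions.
#'
#' @param n_fractions number of fractions, default 33.
#' @param prescription_high high-risk PTV prescription in Gy, default 70.
#' @param prescription_low low-risk PTV prescription in Gy, default 59.4.
#' @return Object of class `course_plan` with per-fraction doses filled in.
#' @examples
#' round(course_plan()$dose_per_fraction_high, 2)  # 2.12
#' @export
course_plan <- function(n_fractions = 33L, prescription_high = 70,
                        prescription_low = 59.4) {
  n_fractions <- as.integer(n_fractions)
  stopifnot(n_fractions >= 1L, prescription_high > 0, prescription_low > 0)
  structure(list(
    n_fractions = n_fractions,
    prescription_high = prescription_high,
    prescription_low = prescription_low,
    dose_per_fraction_high = prescription_high / n_fractions,
    dose_per_fraction_low = prescription_low / n_fractions
  ), class = "course_plan")
}

#' @export
print.course_plan <- function(x, ...) {
  cat(sprintf("<course_plan> %g Gy / %d fx (%.2f Gy/fx) high; %g Gy (%.2f Gy/fx) low\n",
              x$prescription_high, x$n_fractions, x$dose_per_fraction_high,
              x$prescription_low, x$dose_per_fraction_low))
  invisible(x)
}

#' Planning margin recipe
#'
#' CTV = GTV + 5-10 mm (default midpoint 7.5 mm), PTV = CTV + 3 mm, brainstem
#' PRV margin 3 mm, spinal-cord PRV margin 5 mm. The elective margin grows
#' the high-dose CTV into the low-dose (nodal) CTV in the synthetic phantom;
#' it is a phantom construction parameter, not a clinical recipe value.
#'
#' @param ctv_from_gtv cm, default 0.75.
#' @param ptv_from_ctv cm, default 0.3.
#' @param prv_brainstem cm, default 0.3.
#' @param prv_cord cm, default 0.5.
#' @param elective cm, default 1.0 (low-dose CTV from high-dose CTV).
#' @return Object of class `margin_spec`.
#' @export
margin_spec <- function(ctv_from_gtv = 0.75, ptv_from_ctv = 0.3,
                        prv_brainstem = 0.3, prv_cord = 0.5, elective = 1.0) {
  m <- c(ctv_from_gtv, ptv_from_ctv, prv_brainstem, prv_cord, elective)
  if (any(!is.finite(m)) || any(m < 0))
    stop("all margins must be non-negative (cm)", call. = FALSE)
  structure(list(ctv_from_gtv = ctv_from_gtv, ptv_from_ctv = ptv_from_ctv,
                 prv_brainstem = prv_brainstem, prv_cord = prv_cord,
                 elective = elective),
            class = "margin_spec")
}

required_structures <- function() {
  c("external", "gtv_high", "ctv_high", "ctv_low", "ptv_high", "ptv_low",
    "spinal_cord", "spinal_cord_prv", "brainstem", "brainstem_prv")
}

#' Named stack of structure masks on a shared grid
#'
#' Bundles the external body contour and all planning structures of one image
#' (CTsim or a per-fraction assessment) as boolean masks on one voxel grid.
#' Validation enforces: every non-external structure is inside the external,
#' CTV contains GTV, and PTV contains CTV (high and low levels).
#'
#' @param masks named list of logical arrays; must contain at least the
#'   required names returned by `required_structures()` unless
#'   `partial = TRUE`.
#' @param grid the shared [voxel_grid()].
#' @param partial allow a subset of structures (used mid-construction).
#' @return Object of class `structure_set`.
#' @export
structure_set <- function(masks, grid, partial = FALSE) {
  stopifnot(is_voxel_grid(grid), is.list(masks), !is.null(names(masks)))
  for (nm in names(masks)) check_mask(masks[[nm]], grid, nm)
  if (!partial) {
    miss <- setdiff(required_structures(), names(masks))
    if (length(miss))
      stop("missing required structures: ", paste(miss, collapse = ", "),
           call. = FALSE)
    ext <- masks$external
    for (nm in setdiff(names(masks), "external"))
      if (any(masks[[nm]] & !ext))
        stop(sprintf("structure '%s' extends outside the external contour", nm),
             call. = FALSE)
    if (any(masks$gtv_high & !masks$ctv_high))
      stop("ctv_high does not contain gtv_high", call. = FALSE)
    if (any(masks$ctv_high & !masks$ptv_high))
      stop("ptv_high does not contain ctv_high", call. = FALSE)
    if (any(masks$ctv_low & !masks$ptv_low))
      stop("ptv_low does not contain ctv_low", call. = FALSE)
  }
  structure(list(masks = masks, grid = grid), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  v <- vapply(x$masks, sum, numeric(1)) * prod(x$grid$spacing)
  cat("<structure_set> volumes (cm^3):\n")
  print(round(v, 2))
  invisible(x)
}

#' Build planning structures from delineated anatomy
#'
#' Applies the margin recipe: CTV(high) = GTV expanded by the CTV margin and
#' cropped to the external body; CTV(low) = CTV(high) expanded by the
#' elective margin, cropped; PTVs = CTVs expanded by the setup margin; PRVs =
#' spinal cord and brainstem expanded by their margins. All structures are
#' cropped to the external contour so the containment invariants hold (the
#' crop of the CTV to the body surface is configurable via `crop_to_external`).
#'
#' @param gtv gross tumor volume mask; must lie inside `external`.
#' @param external external body contour mask.
#' @param spinal_cord,brainstem organ-at-risk masks.
#' @param grid the shared [voxel_grid()].
#' @param margins a [margin_spec()].
#' @param parotid_left,parotid_right optional parotid masks.
#' @param crop_to_external crop expanded target volumes to the body surface
#'   (default TRUE).
#' @return A validated [structure_set()].
#' @export
build_plan_structures <- function(gtv, external, spinal_cord, brainstem, grid,
                                  margins = margin_spec(),
                                  parotid_left = NULL, parotid_right = NULL,
                                  crop_to_external = TRUE) {
  check_mask(gtv, grid, "gtv"); check_mask(external, grid, "external")
  if (any(gtv & !external))
    stop("GTV is not contained in the external contour", call. = FALSE)
  crop <- function(m) if (crop_to_external) m & external else m
  ctv_high <- crop(expand_margin(gtv, margins$ctv_from_gtv, grid))
  ctv_low <- crop(expand_margin(ctv_high, margins$elective, grid))
  ptv_high <- crop(expand_margin(ctv_high, margins$ptv_from_ctv, grid))
  ptv_low <- crop(expand_margin(ctv_low, margins$ptv_from_ctv, grid))
  masks <- list(
    external = external,
    gtv_high = gtv,
    ctv_high = ctv_high,
    ctv_low = ctv_low,
    ptv_high = ptv_high,
    ptv_low = ptv_low,
    spinal_cord = spinal_cord & external,
    spinal_cord_prv = crop(expand_margin(spinal_cord, margins$prv_cord, grid)),
    brainstem = brainstem & external,
    brainstem_prv = crop(expand_margin(brainstem, margins$prv_brainstem, grid))
  )
  if (!is.null(parotid_left)) masks$parotid_left <- parotid_left & external
  if (!is.null(parotid_right)) masks$parotid_right <- parotid_right & external
  structure_set(masks, grid)
}
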