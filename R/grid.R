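#' Voxel grid geometry
#'
#' A regular 3-D voxel grid shared by all masks and dose grids of a treatment
#' course. Coordinates are in cm in the room (bony) frame: `x` left-right,
#' `y` posterior-anterior, `z` inferior-superior (axial slice axis). The
#' center of voxel `(i, j, k)` is at `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @param shape integer vector `(nx, ny, nz)`, voxel counts per axis.
#' @param spacing numeric vector `(dx, dy, dz)` in cm, strictly positive.
#' @param origin numeric vector, cm, position of the grid corner.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(10, 10, 5), spacing = 0.2)
#' dim(empty_mask(g))
#' @export
voxel_grid <- function(shape, spacing = c(0.1, 0.1, 0.1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three positive voxel counts", call. = FALSE)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be strictly positive (cm)", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g cm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Voxel center coordinates along one axis
#'
#' @param grid a [voxel_grid()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of voxel-center coordinates in cm.
#' @export
grid_centers <- function(grid, axis) {
  stopifnot(is_voxel_grid(grid), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$spacing[axis]
}

#' Coordinate arrays for every voxel center
#'
#' @param grid a [voxel_grid()].
#' @return List of three arrays (`x`, `y`, `z`), each of dimension
#'   `grid$shape`, holding voxel-center coordinates in cm.
#' @export
grid_mesh <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  n <- grid$shape
  xc <- grid_centers(grid, 1)
  yc <- grid_centers(grid, 2)
  zc <- grid_centers(grid, 3)
  list(x = array(rep(xc, times = n[2] * n[3]), dim = n),
       y = array(rep(rep(yc, each = n[1]), times = n[3]), dim = n),
       z = array(rep(zc, each = n[1] * n[2]), dim = n))
}

#' All-FALSE mask on a grid
#' @param grid a [voxel_grid()].
#' @return Logical array of dimension `grid$shape`.
#' @export
empty_mask <- function(grid) {
  stopifnot(is_voxel_grid(grid))
  array(FALSE, dim = grid$shape)
}

check_mask <- function(mask, grid, arg = "mask") {
  if (!is.logical(mask) || !identical(dim(mask), as.integer(grid$shape)))
    stop(sprintf("`%s` must be a logical array matching the grid shape", arg),
         call. = FALSE)
  invisible(TRUE)
}

#' Physical volume of a mask
#' @param mask logical array on `grid`.
#' @param grid a [voxel_grid()].
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @export
mask_volume <- function(mask, grid) {
  check_mask(mask, grid)
  sum(mask) * prod(grid$spacing)
}

# Integer offsets (rows of an n x 3 matrix) whose physical displacement is
# within `margin` cm of the origin, excluding (0,0,0).
margin_offsets <- function(margin, spacing) {
  r <- floor(margin / spacing + 1e-9)
  off <- as.matrix(expand.grid(a = -r[1]:r[1], b = -r[2]:r[2], c = -r[3]:r[3]))
  d2 <- (off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
    (off[, 3] * spacing[3])^2
  off[d2 <= margin^2 + 1e-12 & d2 > 0, , drop = FALSE]
}

# OR `mask` shifted by integer offset (a, b, c) into `acc`.
shift_or <- function(acc, mask, off) {
  n <- dim(mask)
  tx <- max(1L, 1L + off[1]):min(n[1], n[1] + off[1])
  ty <- max(1L, 1L + off[2]):min(n[2], n[2] + off[2])
  tz <- max(1L, 1L + off[3]):min(n[3], n[3] + off[3])
  acc[tx, ty, tz] <- acc[tx, ty, tz, drop = FALSE] |
    mask[tx - off[1], ty - off[2], tz - off[3], drop = FALSE]
  acc
}

#' Isotropic margin expansion of a structure mask
#'
#' Expands a boolean structure mask by a Euclidean margin: the result contains
#' every voxel whose center lies within `margin` cm (3-D distance, anisotropic
#' spacing respected) of the center of some voxel in the input mask. This is
#' the operation used to grow a GTV into a CTV, a CTV into a PTV, and an
#' organ at risk into its planning risk volume (PRV).
#'
#' @param mask logical array on `grid`.
#' @param margin margin in cm, `>= 0`. `0` returns the mask unchanged.
#' @param grid a [voxel_grid()].
#' @return Logical array; always a superset of `mask`.
#' @export
expand_margin <- function(mask, margin, grid) {
  check_mask(mask, grid)
  if (!is.numeric(margin) || length(margin) != 1L || is.na(margin) || margin < 0)
    stop("`margin` must be a single non-negative number (cm)", call. = FALSE)
  if (margin == 0 || !any(mask)) return(mask)
  off <- margin_offsets(margin, grid$spacing)
  out <- mask
  for (i in seq_len(nrow(off))) out <- shift_or(out, mask, off[i, ])
  out
}
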