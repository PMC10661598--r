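#' Calibrated voxel lattice
#'
#' The 3D voxel grid over which the system is calibrated and images are
#' reconstructed. Voxels are point samples at their centers. Counts per
#' axis follow `floor(extent/inc) + 1`, so both endpoints of each stated
#' extent are scanned: a 15 x 15 x 6 mm volume at 0.5 / 0.5 / 0.3 mm
#' increments gives 31 x 31 x 21 = 20181 voxels.
#'
#' The coordinate frame places the pipe entrance disk center at the
#' origin with the pipe axis along +Z; imaging voxels sit at z > 0 in
#' water in front of the entrance plane.
#'
#' @param extent_mm Length-3 physical extents (ex, ey, ez) in mm.
#' @param inc_mm Length-3 voxel pitch (dx, dy, dz) in mm, all positive.
#' @param origin_mm Coordinate of the center of voxel (0,0,0), mm.
#' @return An object of class `volume_grid` with fields `extent_mm`,
#'   `inc_mm`, `origin_mm`, `counts` (nx, ny, nz) and `n` voxels total.
#' @export
#' @examples
#' g <- make_grid(c(15, 15, 6), c(0.5, 0.5, 0.3))
#' g$counts  # 31 31 21
#' g$n       # 20181
make_grid <- function(extent_mm, inc_mm, origin_mm = c(0, 0, 0)) {
  extent_mm <- as.numeric(extent_mm); inc_mm <- as.numeric(inc_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(extent_mm) != 3 || length(inc_mm) != 3 || length(origin_mm) != 3)
    stop("extent_mm, inc_mm and origin_mm must have length 3", call. = FALSE)
  if (any(!is.finite(extent_mm)) || any(extent_mm <= 0))
    stop("all extents must be strictly positive", call. = FALSE)
  if (any(!is.finite(inc_mm)) || any(inc_mm <= 0))
    stop("all increments must be strictly positive", call. = FALSE)
  # epsilon guard: 6/0.3 is 19.999... in binary floating point
  counts <- as.integer(floor(extent_mm / inc_mm + 1e-9)) + 1L
  structure(
    list(extent_mm = extent_mm, inc_mm = inc_mm, origin_mm = origin_mm,
         counts = counts, n = as.integer(prod(counts))),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels (N = %d)\n",
              x$counts[1], x$counts[2], x$counts[3], x$n))
  cat(sprintf("  extent %g x %g x %g mm at pitch %g / %g / %g mm\n",
              x$extent_mm[1], x$extent_mm[2], x$extent_mm[3],
              x$inc_mm[1], x$inc_mm[2], x$inc_mm[3]))
  cat(sprintf("  origin (%g, %g, %g) mm\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

#' Linearize a voxel index triple
#'
#' Maps 0-based axis indices (ix, iy, iz) to the 0-based linear voxel
#' index `i = ix + nx*(iy + ny*iz)`; X varies fastest. This is the shared
#' ordering of dictionary columns and image vectors.
#'
#' @param grid A `volume_grid`.
#' @param ijk Length-3 integer vector of 0-based axis indices.
#' @return 0-based linear index.
#' @seealso [delinearize()], [voxel_center()]
#' @export
linear_index <- function(grid, ijk) {
  ijk <- as.integer(ijk)
  if (length(ijk) != 3 || any(ijk < 0L) || any(ijk >= grid$counts))
    stop("voxel index out of range for grid", call. = FALSE)
  ijk[1] + grid$counts[1] * (ijk[2] + grid$counts[2] * ijk[3])
}

#' Invert the linear voxel index
#'
#' @param grid A `volume_grid`.
#' @param i 0-based linear index in `[0, N)`.
#' @return Length-3 integer vector of 0-based axis indices.
#' @export
delinearize <- function(grid, i) {
  i <- as.integer(i)
  if (length(i) != 1 || i < 0L || i >= grid$n)
    stop("linear index out of range for grid", call. = FALSE)
  nx <- grid$counts[1]; ny <- grid$counts[2]
  c(i %% nx, (i %/% nx) %% ny, i %/% (nx * ny))
}

#' Physical center of a voxel
#'
#' @param grid A `volume_grid`.
#' @param i 0-based linear voxel index.
#' @return Length-3 coordinate (x, y, z) in mm.
#' @export
voxel_center <- function(grid, i) {
  grid$origin_mm + delinearize(grid, i) * grid$inc_mm
}

# N x 3 matrix of all voxel centers in linear-index order (mm).
voxel_centers <- function(grid) {
  nx <- grid$counts[1]; ny <- grid$counts[2]; nz <- grid$counts[3]
  xs <- grid$origin_mm[1] + (seq_len(nx) - 1L) * grid$inc_mm[1]
  ys <- grid$origin_mm[2] + (seq_len(ny) - 1L) * grid$inc_mm[2]
  zs <- grid$origin_mm[3] + (seq_len(nz) - 1L) * grid$inc_mm[3]
  cbind(x = rep(xs, times = ny * nz),
        y = rep(rep(ys, each = nx), times = nz),
        z = rep(zs, each = nx * ny))
}

# inclusive physical bounds of voxel centers per axis; 3x2 matrix (mm)
grid_bounds <- function(grid) {
  lo <- grid$origin_mm
  hi <- grid$origin_mm + (grid$counts - 1L) * grid$inc_mm
  cbind(lo = lo, hi = hi)
}

#' Voxel intensity volume
#'
#' A nonnegative image `x` over a [make_grid()] lattice, stored as a
#' length-N vector in linear-index order (X fastest). This is the unknown
#' of the reconstruction and the output of the phantom generators.
#'
#' @param values Numeric vector of length `grid$n`, all finite.
#' @param grid The `volume_grid` the values live on.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, grid) {
  values <- as.numeric(values)
  if (length(values) != grid$n)
    stop("values length does not match grid voxel count", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  structure(list(values = values, grid = grid), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  nz <- sum(x$values != 0)
  cat(sprintf("<volume_image> %d x %d x %d, %d nonzero voxels, max %.4g\n",
              x$grid$counts[1], x$grid$counts[2], x$grid$counts[3],
              nz, if (length(x$values)) max(x$values) else NA))
  invisible(x)
}

#' Image vector as a 3-D array
#'
#' Reshapes the linear-index vector to an (nx, ny, nz) array; because the
#' linearization is X-fastest, this is a plain dim-assignment and voxel
#' (ix, iy, iz) lands at `arr[ix+1, iy+1, iz+1]`.
#'
#' @param image A `volume_image`.
#' @return A 3-D numeric array.
#' @export
image_array <- function(image) {
  array(image$values, dim = image$grid$counts)
}
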