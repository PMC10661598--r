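# letter stroke rectangles (x0, x1, y0, y1) in a local frame whose
# height is h and width 0.7*h, stroke width s; block capitals.
letter_rects <- function(letter, h, s) {
  w <- 0.7 * h
  switch(letter,
    B = list(c(0, s, 0, h),                      # spine
             c(0, w, h - s, h),                  # top bar
             c(0, w, (h - s) / 2, (h + s) / 2),  # middle bar
             c(0, w, 0, s),                      # bottom bar
             c(w - s, w, 0, h)),                 # right bar
    U = list(c(0, s, 0, h),
             c(w - s, w, 0, h),
             c(0, w, 0, s)),
    stop(sprintf("unsupported letter '%s' (supported: B, U)", letter),
         call. = FALSE))
}

# nearest z slice (0-based) to a depth measured from the first slice
depth_slice <- function(grid, depth_mm) {
  dz <- grid$inc_mm[3]
  iz <- as.integer(round(depth_mm / dz))
  if (depth_mm < -dz / 2 || iz < 0L || iz > grid$counts[3] - 1L)
    stop(sprintf("depth %.3g mm lies outside the grid", depth_mm),
         call. = FALSE)
  iz
}

#' Block-letter phantom
#'
#' Binary raster of a block capital (B or U) in a single Z slice,
#' centered laterally in the grid. Deterministic: equal arguments give
#' identical volumes.
#'
#' @param letter `"B"` or `"U"`.
#' @param height_mm Letter height, mm (width is 0.7 x height).
#' @param stroke_mm Stroke width, mm.
#' @param depth_mm Depth of the letter slice, mm from the first Z slice.
#' @param grid A [make_grid()] lattice.
#' @return A binary [volume_image()].
#' @export
letter_phantom <- function(letter, height_mm, stroke_mm, depth_mm, grid) {
  rects <- letter_rects(letter, height_mm, stroke_mm)
  w <- 0.7 * height_mm
  ext_x <- (grid$counts[1] - 1L) * grid$inc_mm[1]
  ext_y <- (grid$counts[2] - 1L) * grid$inc_mm[2]
  if (w > ext_x + 1e-9 || height_mm > ext_y + 1e-9)
    stop("letter does not fit inside the grid", call. = FALSE)
  iz <- depth_slice(grid, depth_mm)
  # lateral voxel coordinates in the letter-local frame (letter centered)
  xs <- (seq_len(grid$counts[1]) - 1L) * grid$inc_mm[1] - (ext_x - w) / 2
  ys <- (seq_len(grid$counts[2]) - 1L) * grid$inc_mm[2] - (ext_y - height_mm) / 2
  inside <- matrix(FALSE, grid$counts[1], grid$counts[2])
  eps <- 1e-9
  for (r in rects) {
    inside <- inside | outer(xs >= r[1] - eps & xs <= r[2] + eps,
                             ys >= r[3] - eps & ys <= r[4] + eps, `&`)
  }
  vals <- array(0, grid$counts)
  vals[, , iz + 1L] <- inside * 1.0
  volume_image(as.vector(vals), grid)
}

#' Scene with objects at multiple depths
#'
#' Union (voxelwise max) of letter phantoms placed at distinct depths,
#' for single-shot imaging of several objects at once.
#'
#' @param grid A [make_grid()] lattice.
#' @param spec List of lists with fields `letter`, `depth_mm`,
#'   `height_mm`, and optionally `stroke_mm` (default `height_mm / 5`).
#' @return A binary [volume_image()]; all-zero for an empty spec.
#' @export
two_depth_scene <- function(grid, spec) {
  vals <- numeric(grid$n)
  if (length(spec)) {
    slices <- vapply(spec, function(s) depth_slice(grid, s$depth_mm), 0L)
    if (anyDuplicated(slices))
      stop("objects must sit at distinct depths", call. = FALSE)
    for (s in spec) {
      stroke <- if (is.null(s$stroke_mm)) s$height_mm / 5 else s$stroke_mm
      ph <- letter_phantom(s$letter, s$height_mm, stroke, s$depth_mm, grid)
      vals <- pmax(vals, ph$values)
    }
  }
  volume_image(vals, grid)
}

#' Disk phantom
#'
#' Binary cylinder with axis along Z: voxels whose lateral distance to
#' the center is at most `diameter_mm / 2` on the slices whose centers
#' lie within `thickness_mm / 2` of the center depth.
#'
#' @param center_mm Disk center (x, y, z) in grid coordinates, mm.
#' @param diameter_mm Disk diameter, mm (0 gives a single-voxel column).
#' @param thickness_mm Disk thickness along Z, mm.
#' @param grid A [make_grid()] lattice.
#' @return A binary [volume_image()].
#' @export
disk_phantom <- function(center_mm, diameter_mm, thickness_mm, grid) {
  center_mm <- as.numeric(center_mm)
  b <- grid_bounds(grid)
  if (any(center_mm < b[, "lo"] - 1e-9) || any(center_mm > b[, "hi"] + 1e-9))
    stop("disk center lies outside the grid", call. = FALSE)
  if (center_mm[1] - diameter_mm / 2 < b[1, "lo"] - grid$inc_mm[1] / 2 - 1e-9 ||
      center_mm[1] + diameter_mm / 2 > b[1, "hi"] + grid$inc_mm[1] / 2 + 1e-9 ||
      center_mm[2] - diameter_mm / 2 < b[2, "lo"] - grid$inc_mm[2] / 2 - 1e-9 ||
      center_mm[2] + diameter_mm / 2 > b[2, "hi"] + grid$inc_mm[2] / 2 + 1e-9)
    stop("disk does not fit inside the grid", call. = FALSE)
  cn <- voxel_centers(grid)
  lat <- sqrt((cn[, 1] - center_mm[1])^2 + (cn[, 2] - center_mm[2])^2)
  inz <- abs(cn[, 3] - center_mm[3]) <= thickness_mm / 2 + 1e-9
  vals <- as.numeric(lat <= diameter_mm / 2 + 1e-9 & inz)
  if (!any(vals > 0)) {  # degenerate sizes: nearest single-voxel column
    if (!any(inz)) inz <- abs(cn[, 3] - center_mm[3]) <=
        min(abs(cn[, 3] - center_mm[3])) + 1e-9
    ilat <- which.min(lat)  # lowest index wins ties
    vals[inz & cn[, 1] == cn[ilat, 1] & cn[, 2] == cn[ilat, 2]] <- 1
  }
  volume_image(vals, grid)
}

#' Upward spiral trajectory
#'
#' Frame centers on a helix: frame k (0-based) at angle
#' `2*pi*n_turns*k/(n_frames-1)` on a cylinder of given radius, with Z
#' linear from `z_start_mm` to `z_end_mm` (endpoints exact).
#'
#' @param center_mm Lateral center (x, y) of the cylinder axis, mm.
#' @param radius_mm Helix radius, mm (0 gives a vertical line).
#' @param z_start_mm,z_end_mm Z of the first and last frame, mm.
#' @param n_turns Number of full turns over the trajectory.
#' @param n_frames Number of frames (>= 2).
#' @param grid Optional [make_grid()] lattice; if given, every center
#'   must lie inside the grid bounds and offenders are reported.
#' @return `n_frames` x 3 matrix of (x, y, z) centers, mm.
#' @export
spiral_trajectory <- function(center_mm, radius_mm, z_start_mm, z_end_mm,
                              n_turns, n_frames, grid = NULL) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (radius_mm < 0) stop("radius_mm must be >= 0", call. = FALSE)
  k <- seq_len(n_frames) - 1L
  ang <- 2 * pi * n_turns * k / (n_frames - 1L)
  pts <- cbind(x = center_mm[1] + radius_mm * cos(ang),
               y = center_mm[2] + radius_mm * sin(ang),
               z = z_start_mm + (z_end_mm - z_start_mm) * k / (n_frames - 1L))
  if (!is.null(grid)) {
    b <- grid_bounds(grid)
    bad <- which(pts[, 1] < b[1, 1] - 1e-9 | pts[, 1] > b[1, 2] + 1e-9 |
                 pts[, 2] < b[2, 1] - 1e-9 | pts[, 2] > b[2, 2] + 1e-9 |
                 pts[, 3] < b[3, 1] - 1e-9 | pts[, 3] > b[3, 2] + 1e-9)
    if (length(bad))
      stop(sprintf("trajectory leaves the grid at frame(s) %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  pts
}

#' Single-voxel point target
#'
#' The calibration "point object": the voxel nearest to a coordinate set
#' to 1 (ties broken toward the lower index on each axis).
#'
#' @param coord_mm Target coordinate (x, y, z), mm.
#' @param grid A [make_grid()] lattice.
#' @return A [volume_image()] with exactly one voxel equal to 1.
#' @export
point_target <- function(coord_mm, grid) {
  coord_mm <- as.numeric(coord_mm)
  b <- grid_bounds(grid)
  if (any(coord_mm < b[, "lo"] - grid$inc_mm / 2 - 1e-9) ||
      any(coord_mm > b[, "hi"] + grid$inc_mm / 2 + 1e-9))
    stop("coordinate lies outside the grid", call. = FALSE)
  rel <- (coord_mm - grid$origin_mm) / grid$inc_mm
  ijk <- pmin(pmax(as.integer(ceiling(rel - 0.5)), 0L), grid$counts - 1L)
  vals <- numeric(grid$n)
  vals[linear_index(grid, ijk) + 1L] <- 1
  volume_image(vals, grid)
}
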