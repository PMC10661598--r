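#' Wrap an existing matrix as a calibration dictionary
#'
#' Builds a `calibration_dictionary` object around a T x N matrix whose
#' columns are already in linear-index order for `grid`. Used for
#' externally supplied or synthetic test dictionaries.
#'
#' @param columns T x N numeric matrix.
#' @param grid The [make_grid()] lattice (`grid$n` must equal N).
#' @param params An [acoustic_params()]; defaults to the standard
#'   parameters with `n_samples` matching the matrix.
#' @param encoder Optional [encoder_config()] provenance.
#' @return A `calibration_dictionary`.
#' @export
dictionary_from_matrix <- function(columns, grid,
                                   params = acoustic_params(n_samples = nrow(columns)),
                                   encoder = NULL) {
  columns <- as.matrix(columns)
  if (ncol(columns) != grid$n)
    stop("column count does not match grid voxel count", call. = FALSE)
  if (!all(is.finite(columns)))
    stop("dictionary columns must be finite", call. = FALSE)
  structure(list(columns = columns, grid = grid, params = params,
                 encoder = encoder, column_norms = NULL, normalized = FALSE),
            class = "calibration_dictionary")
}

#' Standard imaging grids
#'
#' The two lattices used throughout the package, both at the calibrated
#' scan increments (0.5 mm laterally, 0.3 mm axially) and standing 20 mm
#' in front of the pipe entrance, laterally centered on its axis:
#' * `"desk"` — 15 x 15 x 11 voxels (7 x 7 x 3 mm), small enough that
#'   the full calibrate/synthesize/reconstruct pipeline runs in seconds;
#' * `"tracking"` — 31 x 31 x 11 voxels (15 x 15 x 3 mm), the full
#'   lateral calibration field with a 3 mm depth slab, sized so a 5 mm
#'   disk on a radius-3 mm spiral stays inside the volume;
#' * `"full"` — 31 x 31 x 21 voxels (15 x 15 x 6 mm), the complete
#'   calibration volume (N = 20181).
#'
#' @param scale One of `"desk"`, `"tracking"`, `"full"`.
#' @param standoff_mm Distance from the entrance plane to the first
#'   voxel slice, mm.
#' @return A [make_grid()] lattice.
#' @export
default_grid <- function(scale = c("desk", "tracking", "full"),
                         standoff_mm = 20) {
  scale <- match.arg(scale)
  ext <- switch(scale,
                desk = c(7, 7, 3),
                tracking = c(15, 15, 3),
                full = c(15, 15, 6))
  make_grid(ext, c(0.5, 0.5, 0.3),
            origin_mm = c(-ext[1] / 2, -ext[2] / 2, standoff_mm))
}
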