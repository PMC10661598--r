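SCHEMA_VERSION <- "patwist-1"

h5_ensure_group <- function(file, group) {
  parts <- strsplit(group, "/", fixed = TRUE)[[1]]
  fid <- rhdf5::H5Fopen(file)
  on.exit(rhdf5::H5Fclose(fid))
  path <- ""
  for (p in parts) {
    path <- paste0(path, if (nzchar(path)) "/", p)
    if (!rhdf5::H5Lexists(fid, path))
      rhdf5::H5Gclose(rhdf5::H5Gcreate(fid, path))
  }
}

h5_write_list <- function(file, group, x) {
  h5_ensure_group(file, group)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.null(v)) next
    if (is.logical(v)) v <- as.integer(v)
    rhdf5::h5write(v, file, paste0(group, "/", nm))
  }
}

h5_read_list <- function(file, group) {
  out <- rhdf5::h5read(file, group)
  lapply(out, function(v) if (is.array(v) && length(dim(v)) == 1L) as.vector(v) else v)
}

grid_from_meta <- function(m) {
  make_grid(as.numeric(m$extent_mm), as.numeric(m$inc_mm),
            as.numeric(m$origin_mm))
}

params_from_meta <- function(m) {
  acoustic_params(v_water = m$v_water, v_pipe = m$v_pipe, f_c = m$f_c,
                  frac_bw_6db = m$frac_bw_6db, pipe_length = m$pipe_length,
                  pipe_radius = m$pipe_radius, fs = m$fs,
                  n_samples = m$n_samples)
}

encoder_from_meta <- function(m) {
  encoder_config(coda_len = m$coda_len, coda_decay_tau = m$coda_decay_tau,
                 lateral_fwhm_mm = m$lateral_fwhm_mm,
                 calib_snr_db = if (m$calib_snr_db_finite == 0) Inf else m$calib_snr_db,
                 n_avg = m$n_avg, seed = m$seed)
}

#' Persist package objects to an HDF5 container
#'
#' Writes any of a dictionary, named signals, named images, and a
#' reconstruction result into one HDF5 file: `/dictionary` (T x N,
#' chunked), `/signals/<name>` (1-D), `/images/<name>` (3-D, stored as
#' (nz, ny, nx) so voxel (ix, iy, iz) is at `[iz, iy, ix]`), plus
#' metadata groups for the grid, acoustic parameters, encoder and solver
#' configurations, and a root `schema_version` attribute. Round-trips
#' losslessly through [load_container()].
#'
#' @param path Output file path (overwritten if present).
#' @param dictionary Optional `calibration_dictionary`.
#' @param signals Named list of [measured_signal()]s.
#' @param images Named list of [volume_image()]s.
#' @param result Optional `recon_result` (stores its image under
#'   `images/<result_name>` plus the objective trace and config).
#' @param result_name Image name used for `result`.
#' @param provenance Named list of scalars (seeds, SNRs, command
#'   parameters) recording how the artifact was produced; stored under
#'   `/provenance`.
#' @return `path`, invisibly.
#' @export
save_container <- function(path, dictionary = NULL, signals = list(),
                           images = list(), result = NULL,
                           result_name = "xhat", provenance = list()) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(SCHEMA_VERSION, fid, "schema_version")
  rhdf5::H5Fclose(fid)

  grid <- NULL
  if (!is.null(dictionary)) {
    M <- dictionary$columns
    rhdf5::h5createDataset(path, "dictionary", dims = dim(M),
                           chunk = c(nrow(M), 1L), level = 0L)
    rhdf5::h5write(M, path, "dictionary")
    if (!is.null(dictionary$column_norms))
      rhdf5::h5write(dictionary$column_norms, path, "column_norms")
    p <- dictionary$params
    h5_write_list(path, "params",
                  list(v_water = p$v_water, v_pipe = p$v_pipe, f_c = p$f_c,
                       frac_bw_6db = p$frac_bw_6db,
                       pipe_length = p$pipe_length,
                       pipe_radius = p$pipe_radius, fs = p$fs,
                       n_samples = p$n_samples,
                       normalized = dictionary$normalized))
    e <- dictionary$encoder
    if (!is.null(e))
      h5_write_list(path, "encoder",
                    list(coda_len = e$coda_len,
                         coda_decay_tau = e$coda_decay_tau,
                         lateral_fwhm_mm = e$lateral_fwhm_mm,
                         calib_snr_db = if (is.finite(e$calib_snr_db)) e$calib_snr_db else 0,
                         calib_snr_db_finite = is.finite(e$calib_snr_db),
                         n_avg = e$n_avg, seed = e$seed))
    grid <- dictionary$grid
  }
  if (!is.null(result)) images[[result_name]] <- result$image
  if (length(images)) rhdf5::h5createGroup(path, "images")
  for (nm in names(images)) {
    im <- images[[nm]]
    if (is.null(grid)) grid <- im$grid
    if (!identical(im$grid$counts, grid$counts))
      stop("all images in one container must share a grid", call. = FALSE)
    rhdf5::h5write(aperm(image_array(im), c(3, 2, 1)), path,
                   paste0("images/", nm))
  }
  if (!is.null(result)) {
    rhdf5::h5write(result$objective_trace, path, "objective_trace")
    cfg <- result$config
    h5_write_list(path, "solver",
                  list(lam = cfg$lam, max_iter = cfg$max_iter, tol = cfg$tol,
                       tv_inner_iter = cfg$tv_inner_iter, xi = cfg$xi,
                       nonneg = cfg$nonneg,
                       n_iter = result$n_iter, converged = result$converged))
  }
  if (length(signals)) rhdf5::h5createGroup(path, "signals")
  for (nm in names(signals)) {
    s <- signals[[nm]]
    rhdf5::h5write(s$samples, path, paste0("signals/", nm))
    h5_write_list(path, paste0("signals_meta/", nm),
                  list(fs = s$fs, pulse_energy = s$pulse_energy))
  }
  if (!is.null(grid))
    h5_write_list(path, "grid",
                  list(extent_mm = grid$extent_mm, inc_mm = grid$inc_mm,
                       origin_mm = grid$origin_mm))
  if (length(provenance)) h5_write_list(path, "provenance", provenance)
  invisible(path)
}

#' Load an HDF5 container written by [save_container()]
#'
#' @param path File path.
#' @return A list with any of `dictionary`, `signals`, `images`,
#'   `objective_trace`, `solver`, `grid` that the file contains.
#' @export
load_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  schema <- rhdf5::h5readAttributes(path, "/")$schema_version
  if (is.null(schema) || !identical(as.character(schema), SCHEMA_VERSION))
    stop("schema mismatch: file lacks schema_version '", SCHEMA_VERSION, "'",
         call. = FALSE)
  ls_ <- rhdf5::h5ls(path)
  top <- ls_$name[ls_$group == "/"]
  out <- list()
  grid <- if ("grid" %in% top) grid_from_meta(h5_read_list(path, "grid"))
  out$grid <- grid
  if ("dictionary" %in% top) {
    M <- rhdf5::h5read(path, "dictionary")
    pm <- h5_read_list(path, "params")
    params <- params_from_meta(pm)
    enc <- if ("encoder" %in% top) encoder_from_meta(h5_read_list(path, "encoder"))
    d <- dictionary_from_matrix(M, grid, params, enc)
    if ("column_norms" %in% top) {
      d$column_norms <- as.vector(rhdf5::h5read(path, "column_norms"))
      d$normalized <- as.logical(pm$normalized)
    }
    out$dictionary <- d
  }
  if ("signals" %in% top) {
    nms <- ls_$name[ls_$group == "/signals"]
    out$signals <- stats::setNames(lapply(nms, function(nm) {
      meta <- h5_read_list(path, paste0("signals_meta/", nm))
      measured_signal(as.vector(rhdf5::h5read(path, paste0("signals/", nm))),
                      fs = meta$fs, pulse_energy = meta$pulse_energy)
    }), nms)
  }
  if ("images" %in% top) {
    nms <- ls_$name[ls_$group == "/images"]
    out$images <- stats::setNames(lapply(nms, function(nm) {
      a <- rhdf5::h5read(path, paste0("images/", nm))
      volume_image(as.vector(aperm(a, c(3, 2, 1))), grid)
    }), nms)
  }
  if ("objective_trace" %in% top)
    out$objective_trace <- as.vector(rhdf5::h5read(path, "objective_trace"))
  if ("solver" %in% top) out$solver <- h5_read_list(path, "solver")
  if ("provenance" %in% top) out$provenance <- h5_read_list(path, "provenance")
  out
}
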