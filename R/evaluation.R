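#' Full width at half maximum of a sampled profile
#'
#' Locates the unique global maximum and the half-maximum crossings on
#' either side by linear interpolation between samples. A single-sample
#' peak whose profile offers no crossings (profile of length 1) is
#' assigned one sample spacing by convention.
#'
#' @param profile_values Numeric profile samples.
#' @param spacing_mm Sample spacing, mm.
#' @return FWHM in mm.
#' @export
fwhm <- function(profile_values, spacing_mm) {
  p <- as.numeric(profile_values)
  if (!length(p) || all(p == 0)) stop("all-zero profile", call. = FALSE)
  pk <- max(p)
  if (pk <= 0) stop("profile has no positive peak", call. = FALSE)
  im <- which(p == pk)
  if (length(im) > 1L)
    stop("profile has no unique global maximum", call. = FALSE)
  if (length(p) == 1L) return(spacing_mm)
  half <- pk / 2
  cross <- function(idx_seq) {
    # walk from the peak outward; return distance (in samples) to the
    # interpolated half-max crossing
    prev <- im
    for (j in idx_seq) {
      if (p[j] <= half) {
        frac <- (p[prev] - half) / (p[prev] - p[j])
        return(abs(j - prev) * frac + abs(prev - im))
      }
      prev <- j
    }
    NA_real_
  }
  left <- if (im > 1L) cross((im - 1L):1L) else NA_real_
  right <- if (im < length(p)) cross((im + 1L):length(p)) else NA_real_
  if (is.na(left) && is.na(right))
    stop("profile never falls below half maximum", call. = FALSE)
  # one-sided profile (peak at the boundary): mirror the measured side
  if (is.na(left)) left <- right
  if (is.na(right)) right <- left
  (left + right) * spacing_mm
}

#' Point-spread resolution of the reconstruction
#'
#' Reconstructs a point target at the center voxel of the calibrated
#' grid from its synthetic single-shot trace and returns the FWHM of the
#' intensity profile through the reconstruction argmax along the
#' requested axis (X for lateral, Z for axial).
#'
#' @param K A `calibration_dictionary`.
#' @param cfg A [recon_config()].
#' @param axis `"lateral"` or `"axial"`.
#' @param snr_db SNR of the synthetic trace (default `Inf`, noiseless).
#' @param seed Optional noise seed.
#' @return FWHM in mm.
#' @export
measure_resolution <- function(K, cfg, axis = c("lateral", "axial"),
                               snr_db = Inf, seed = NULL) {
  axis <- match.arg(axis)
  g <- K$grid
  center_ijk <- (g$counts - 1L) %/% 2L
  target <- point_target(g$origin_mm + center_ijk * g$inc_mm, g)
  y <- synthesize(K, target, snr_db = snr_db, seed = seed)
  rec <- twist_reconstruct(y, K, cfg)
  arr <- image_array(rec$image)
  am <- arrayInd(which.max(arr), dim(arr))
  if (axis == "lateral")
    fwhm(arr[, am[2], am[3]], g$inc_mm[1])
  else
    fwhm(arr[am[1], am[2], ], g$inc_mm[3])
}

#' Two-point resolution criterion
#'
#' Rayleigh-like dip test: two points count as resolved when the
#' intensity at the voxel nearest their midpoint is at most 73.5% of
#' the smaller of the two peak-voxel intensities.
#'
#' @param image A reconstructed [volume_image()].
#' @param p1_mm,p2_mm The two point locations, mm.
#' @param dip_frac Dip threshold (default 0.735).
#' @return `TRUE` if resolved.
#' @export
two_point_resolved <- function(image, p1_mm, p2_mm, dip_frac = 0.735) {
  g <- image$grid
  at <- function(coord) {
    t <- point_target(coord, g)  # validates bounds, nearest-voxel rule
    image$values[which(t$values == 1)]
  }
  v1 <- at(p1_mm); v2 <- at(p2_mm)
  vm <- at((as.numeric(p1_mm) + as.numeric(p2_mm)) / 2)
  vm <= dip_frac * min(v1, v2)
}

#' Centroid of the object pixels
#'
#' Unweighted mean of the coordinates of the voxels whose intensity is
#' at least `thresh_frac` times the image maximum — the "object pixels"
#' used for position estimation of a tracked object.
#'
#' @param image A [volume_image()].
#' @param thresh_frac Fraction of the maximum defining object pixels
#'   (default 0.5).
#' @return Length-3 centroid (x, y, z) in mm.
#' @export
centroid <- function(image, thresh_frac = 0.5) {
  mx <- max(image$values)
  if (mx <= 0) stop("empty image: no positive voxels", call. = FALSE)
  sel <- image$values >= thresh_frac * mx
  unname(colMeans(voxel_centers(image$grid)[sel, , drop = FALSE]))
}

#' Track a moving object over frames
#'
#' For each frame center: render the object (a disk), synthesize its
#' single-shot trace at the requested SNR, reconstruct, and estimate the
#' position as the thresholded centroid. Reports per-axis signed mean
#' and standard deviation of (estimate - truth) over frames.
#'
#' @param K A `calibration_dictionary`.
#' @param trajectory `n_frames` x 3 matrix of true centers, mm (e.g.
#'   from [spiral_trajectory()]).
#' @param object_spec List with `diameter_mm` and `thickness_mm` of the
#'   tracked disk.
#' @param cfg A [recon_config()].
#' @param snr_db Per-frame trace SNR, dB.
#' @param seed Base RNG seed; frame k uses a seed derived from it, so
#'   frames are independent and order-insensitive.
#' @param thresh_frac Object-pixel threshold for [centroid()].
#' @return An object of class `tracking_result` with `est_centers`,
#'   `true_centers`, `per_axis_mean`, `per_axis_sd` (mm).
#' @export
track <- function(K, trajectory, object_spec, cfg, snr_db = Inf,
                  seed = NULL, thresh_frac = 0.5) {
  trajectory <- as.matrix(trajectory)
  nf <- nrow(trajectory)
  est <- matrix(NA_real_, nf, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (k in seq_len(nf)) {
    ph <- tryCatch(
      disk_phantom(trajectory[k, ], object_spec$diameter_mm,
                   object_spec$thickness_mm, K$grid),
      error = function(e) stop(sprintf("frame %d: %s", k, conditionMessage(e)),
                               call. = FALSE))
    y <- synthesize(K, ph, snr_db = snr_db,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, k))
    rec <- twist_reconstruct(y, K, cfg)
    est[k, ] <- centroid(rec$image, thresh_frac)
  }
  d <- est - trajectory
  structure(list(est_centers = est, true_centers = trajectory,
                 per_axis_mean = colMeans(d),
                 per_axis_sd = apply(d, 2, stats::sd)),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("<tracking_result> %d frames\n", nrow(x$est_centers)))
  cat(sprintf("  discrepancy (est - truth): %s\n",
              paste(sprintf("%s %.2f +/- %.2f mm", c("X", "Y", "Z"),
                            x$per_axis_mean, x$per_axis_sd),
                    collapse = ", ")))
  invisible(x)
}

#' Perturb a dictionary to emulate day-to-day calibration drift
#'
#' Applies, independently per column: a sub-sample time shift drawn from
#' `N(0, delay_jitter_ns)` (implemented as an FFT phase ramp, safe for
#' responses that end before the record does), an amplitude scale from
#' `N(1, gain_drift_frac)`, and additive white noise with norm
#' `noise_frac` times the column norm. All-zero magnitudes return the
#' dictionary unchanged.
#'
#' @param K A `calibration_dictionary`.
#' @param delay_jitter_ns Std dev of the per-column delay jitter, ns.
#' @param gain_drift_frac Std dev of the per-column gain factor.
#' @param noise_frac Additive noise norm as a fraction of column norm.
#' @param seed RNG seed.
#' @return The perturbed dictionary.
#' @export
drift_perturb <- function(K, delay_jitter_ns, gain_drift_frac, noise_frac,
                          seed = NULL) {
  stopifnot(delay_jitter_ns >= 0, gain_drift_frac >= 0, noise_frac >= 0)
  if (delay_jitter_ns == 0 && gain_drift_frac == 0 && noise_frac == 0)
    return(K)
  M <- K$columns
  T_ <- nrow(M); N <- ncol(M)
  fs <- K$params$fs
  with_seed(seed, {
    if (delay_jitter_ns > 0) {
      delays <- stats::rnorm(N, sd = delay_jitter_ns * 1e-9)
      f <- c(0:(T_ %/% 2), -((T_ - T_ %/% 2 - 1L):1)) * fs / T_
      F <- stats::mvfft(M)
      F <- F * exp(-2i * pi * outer(f, delays))
      M <- Re(stats::mvfft(F, inverse = TRUE)) / T_
    }
    if (gain_drift_frac > 0)
      M <- sweep(M, 2, stats::rnorm(N, mean = 1, sd = gain_drift_frac), "*")
    if (noise_frac > 0) {
      cn <- sqrt(colSums(M^2))
      M <- M + matrix(stats::rnorm(T_ * N), T_, N) *
        rep(noise_frac * cn / sqrt(T_), each = T_)
    }
  })
  K$columns <- M
  K$column_norms <- NULL
  K$normalized <- FALSE
  K
}

#' Pearson correlation between two volumes
#'
#' Voxelwise Pearson correlation, the fidelity metric used to compare a
#' reconstruction against ground truth or against a reference
#' reconstruction (e.g. in drift studies).
#'
#' @param a,b [volume_image()]s on the same grid (or equal-length
#'   numeric vectors).
#' @return Pearson r.
#' @export
image_correlation <- function(a, b) {
  av <- if (inherits(a, "volume_image")) a$values else as.numeric(a)
  bv <- if (inherits(b, "volume_image")) b$values else as.numeric(b)
  if (length(av) != length(bv))
    stop("images must live on the same grid", call. = FALSE)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  stats::cor(av, bv)
}
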