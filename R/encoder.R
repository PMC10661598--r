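#' Synthetic encoder configuration
#'
#' Parameters of the phenomenological spatio-temporal encoder model used
#' to build calibration dictionaries: each voxel's impulse response is a
#' time-of-flight-delayed band-limited pulse convolved with a
#' voxel-specific pseudorandom scrambling coda, weighted by the
#' critical-angle aperture coupling, mixed laterally to the system's
#' finite lateral resolution, and finally degraded by calibration-shot
#' noise with averaging.
#'
#' @param coda_len Length of the scrambling coda, samples (>= 0; 0
#'   disables scrambling and leaves a pure delayed pulse). The default
#'   100 us coda keeps the per-voxel codes incoherent: after band-pass
#'   filtering by the transducer the code retains roughly
#'   `2 * bandwidth * duration` degrees of freedom, and the default
#'   length keeps worst-case pair correlations well below 0.5 across the
#'   calibrated volume.
#' @param coda_decay_tau Exponential envelope time constant of the
#'   multipath reverberation, seconds.
#' @param lateral_fwhm_mm FWHM of the Gaussian lateral mixing kernel in
#'   the X-Y plane, mm. Default 2.5, the system's measured lateral
#'   resolution (about half the acoustic wavelength in fused silica at
#'   1 MHz).
#' @param calib_snr_db SNR of each calibration shot, dB (`Inf` for
#'   noiseless calibration).
#' @param n_avg Number of averaged acquisitions per calibration point
#'   (default 2, the acquisition protocol's repeat count).
#' @param seed Integer RNG seed; every stochastic element of the encoder
#'   (codas, calibration noise) derives deterministically from it.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(coda_len = 2000L, coda_decay_tau = 100e-6,
                           lateral_fwhm_mm = 2.5, calib_snr_db = 40,
                           n_avg = 2L, seed = 7L) {
  coda_len <- as.integer(coda_len)
  if (coda_len < 0L) stop("coda_len must be >= 0", call. = FALSE)
  if (lateral_fwhm_mm < 0) stop("lateral_fwhm_mm must be >= 0", call. = FALSE)
  n_avg <- as.integer(n_avg)
  if (n_avg < 1L) stop("n_avg must be >= 1", call. = FALSE)
  if (coda_decay_tau <= 0) stop("coda_decay_tau must be positive", call. = FALSE)
  structure(list(coda_len = coda_len, coda_decay_tau = coda_decay_tau,
                 lateral_fwhm_mm = lateral_fwhm_mm,
                 calib_snr_db = calib_snr_db, n_avg = n_avg,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Band-limited transducer impulse waveform
#'
#' Gaussian-envelope cosine at the transducer center frequency whose
#' power spectrum has a -6 dB full width of `frac_bw_6db * f_c`, sampled
#' at `fs` and normalized to unit Euclidean norm.
#'
#' @param params An [acoustic_params()] object.
#' @return Numeric waveform vector (odd length, envelope peak centered).
#' @export
transducer_pulse <- function(params) {
  if (!(params$fs > 2 * params$f_c * (1 + params$frac_bw_6db / 2)))
    stop("sampling rate below Nyquist for the transducer band", call. = FALSE)
  bw_hz <- params$frac_bw_6db * params$f_c
  # power spectrum ~ exp(-(f-f_c)^2/sigma_f^2); -6 dB full width solves
  # exp(-(bw/2)^2/sigma_f^2) = 10^-0.6
  sigma_f <- bw_hz / (2 * sqrt(0.6 * log(10)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(4.5 * sigma_t * params$fs)
  t <- (-half:half) / params$fs
  w <- cos(2 * pi * params$f_c * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(w^2))
}

#' Critical angle of water-to-pipe coupling
#'
#' The incidence angle beyond which acoustic waves from water cannot
#' couple into the faster pipe material: `sin(theta_c) = v_water/v_pipe`.
#'
#' @param params An [acoustic_params()] object.
#' @return Angle in radians.
#' @export
#' @examples
#' critical_angle(acoustic_params()) * 180 / pi  # 14.73
critical_angle <- function(params) {
  if (params$v_water >= params$v_pipe)
    stop("no critical angle: v_water must be < v_pipe", call. = FALSE)
  asin(params$v_water / params$v_pipe)
}

#' Time of flight from a voxel to the detector
#'
#' Water-path propagation from the voxel to the pipe entrance center
#' plus the fixed transit time through the pipe. Axial position is thus
#' encoded in the arrival time of the response.
#'
#' @param coord_mm Voxel coordinate (x, y, z) in mm; the entrance disk
#'   center is at the origin and the voxel must lie at z >= 0.
#' @param params An [acoustic_params()] object.
#' @return Delay in seconds.
#' @export
time_of_flight <- function(coord_mm, params) {
  coord_mm <- as.numeric(coord_mm)
  if (coord_mm[3] < 0)
    stop("voxel lies behind the pipe entrance plane", call. = FALSE)
  d_m <- sqrt(sum(coord_mm^2)) * 1e-3
  d_m / params$v_water + params$pipe_length / params$v_pipe
}

#' Aperture coupling weight of a voxel
#'
#' Fraction of the acoustic energy radiated by a point source that
#' couples into the relay pipe: the solid angle of rays that both hit
#' the entrance disk and make an angle of at most the critical angle
#' with the pipe axis, normalized so an on-axis voxel whose view of the
#' disk exceeds the critical cone gets `(1 - cos(theta_c)) / 2`. For an
#' on-axis voxel at distance `d`, this equals `(1 - cos(theta_eff)) / 2`
#' with `theta_eff = min(theta_c, atan(pipe_radius / d))`; off-axis
#' voxels are handled by the same geometric acceptance, integrated by
#' quadrature over the polar angle with a closed-form azimuthal
#' fraction.
#'
#' @param coord_mm Voxel coordinate (x, y, z) in mm; z must be > 0.
#' @param params An [acoustic_params()] object.
#' @param n_quad Quadrature points over the polar angle.
#' @return Weight in `[0, (1 - cos(theta_c)) / 2]`.
#' @export
aperture_weight <- function(coord_mm, params, n_quad = 256L) {
  coord_mm <- as.numeric(coord_mm)
  z <- coord_mm[3]
  if (z <= 0)
    stop("voxel must lie at positive distance in front of the entrance plane",
         call. = FALSE)
  rho <- sqrt(coord_mm[1]^2 + coord_mm[2]^2)
  r <- params$pipe_radius * 1e3
  thc <- critical_angle(params)
  dth <- thc / n_quad
  th <- (seq_len(n_quad) - 0.5) * dth
  a <- z * tan(th)  # lateral displacement of the ray footprint
  frac <- if (rho < 1e-12) {
    as.numeric(a <= r)
  } else {
    cc <- (r^2 - rho^2 - a^2) / (2 * rho * a)
    ifelse(cc >= 1, 1, ifelse(cc <= -1, 0, (pi - acos(pmax(-1, pmin(1, cc)))) / pi))
  }
  0.5 * sum(sin(th) * frac) * dth
}

#' Pseudorandom scrambling coda of a voxel
#'
#' The voxel-specific temporal code imposed by multipath scrambling in
#' the relay: white Gaussian samples under an exponentially decaying
#' envelope, unit-normalized, seeded deterministically by the encoder
#' seed and the voxel index so that calibration is exactly reproducible.
#'
#' @param i 0-based voxel index.
#' @param encoder An [encoder_config()].
#' @param params An [acoustic_params()] object (for the sample interval).
#' @return Numeric waveform of length `encoder$coda_len`; a single-sample
#'   unit impulse when `coda_len == 1`.
#' @export
scramble_coda <- function(i, encoder, params) {
  len <- encoder$coda_len
  if (len < 1L) stop("coda_len must be >= 1", call. = FALSE)
  if (len == 1L) return(1.0)
  w <- with_seed(derive_seed(encoder$seed, i), stats::rnorm(len))
  t <- (seq_len(len) - 1L) / params$fs
  w <- w * exp(-t / encoder$coda_decay_tau)
  w / sqrt(sum(w^2))
}

# full linear convolution via FFT
conv_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  L <- stats::nextn(n, 2)
  fa <- stats::fft(c(a, rep(0, L - length(a))))
  fb <- stats::fft(c(b, rep(0, L - length(b))))
  Re(stats::fft(fa * fb, inverse = TRUE))[seq_len(n)] / L
}

#' Build a synthetic calibration dictionary
#'
#' Emulates pointwise calibration of the imaging volume: for every voxel
#' i the column is the aperture-weighted, time-of-flight-delayed
#' transducer pulse convolved with that voxel's scrambling coda; columns
#' are then laterally mixed to the encoder's finite lateral resolution,
#' and finally each column is the average of `n_avg` noisy calibration
#' shots at `calib_snr_db`.
#'
#' @param grid A [make_grid()] lattice (voxels at z > 0).
#' @param params An [acoustic_params()] object.
#' @param encoder An [encoder_config()].
#' @return An object of class `calibration_dictionary` with fields
#'   `columns` (T x N matrix), `grid`, `params`, `encoder`,
#'   `column_norms` (set after [normalize_columns()]), `normalized`.
#' @export
build_dictionary <- function(grid, params, encoder) {
  centers <- voxel_centers(grid)
  pulse <- transducer_pulse(params)
  T_ <- params$n_samples
  N <- grid$n
  K <- matrix(0, nrow = T_, ncol = N)
  use_coda <- encoder$coda_len >= 1L
  for (i in seq_len(N)) {
    cm <- centers[i, ]
    w <- aperture_weight(cm, params)
    tof <- time_of_flight(cm, params)
    shift <- as.integer(round(tof * params$fs))
    sig <- if (use_coda) conv_full(pulse, scramble_coda(i - 1L, encoder, params)) else pulse
    if (shift + length(sig) > T_)
      stop(sprintf("response of voxel %d (0-based) at (%.2f, %.2f, %.2f) mm exceeds the record length",
                   i - 1L, cm[1], cm[2], cm[3]), call. = FALSE)
    K[shift + seq_along(sig), i] <- w * sig
  }
  K <- lateral_mix(K, grid, encoder$lateral_fwhm_mm)
  if (is.finite(encoder$calib_snr_db)) {
    pw <- colMeans(K^2)
    sd_col <- sqrt(pw * 10^(-encoder$calib_snr_db / 10))
    acc <- matrix(0, T_, N)
    with_seed(derive_seed(encoder$seed, 2^20), {
      for (r in seq_len(encoder$n_avg)) {
        noise <- matrix(stats::rnorm(T_ * N), T_, N)
        acc <- acc + K + noise * rep(sd_col, each = T_)
      }
    })
    K <- acc / encoder$n_avg
  }
  structure(list(columns = K, grid = grid, params = params,
                 encoder = encoder, column_norms = NULL,
                 normalized = FALSE),
            class = "calibration_dictionary")
}

#' @export
print.calibration_dictionary <- function(x, ...) {
  cat(sprintf("<calibration_dictionary> %d samples x %d voxels%s\n",
              nrow(x$columns), ncol(x$columns),
              if (x$normalized) " (unit columns)" else ""))
  print(x$grid)
  invisible(x)
}

#' Mix dictionary columns to a finite lateral resolution
#'
#' Replaces each column by the Gaussian-weighted mixture of the columns
#' of laterally neighboring voxels in the same Z slice (kernel FWHM
#' `lateral_fwhm_mm` in the X-Y plane, weights normalized to sum 1 per
#' voxel). FWHM 0 is the identity. This imposes the half-wavelength-scale
#' lateral blur of the physical encoder on the synthetic dictionary.
#'
#' @param K_raw T x N numeric matrix of raw columns.
#' @param grid The `volume_grid` the columns are ordered by.
#' @param lateral_fwhm_mm Kernel FWHM, mm.
#' @return T x N mixed matrix.
#' @export
lateral_mix <- function(K_raw, grid, lateral_fwhm_mm) {
  if (lateral_fwhm_mm <= 0) return(K_raw)
  sigma <- lateral_fwhm_mm / (2 * sqrt(2 * log(2)))
  axis_op <- function(n, pitch) {
    pos <- (seq_len(n) - 1L) * pitch
    D <- outer(pos, pos, function(a, b) abs(a - b))
    W <- exp(-D^2 / (2 * sigma^2))
    W[D > 3 * sigma] <- 0
    W / rowSums(W)
  }
  Wx <- axis_op(grid$counts[1], grid$inc_mm[1])
  Wy <- axis_op(grid$counts[2], grid$inc_mm[2])
  Wxy <- Matrix::Matrix(kronecker(Wy, Wx), sparse = TRUE)
  W3t <- Matrix::kronecker(Matrix::Diagonal(grid$counts[3]), Matrix::t(Wxy))
  as.matrix(K_raw %*% W3t)
}

#' Add white Gaussian noise at a requested SNR
#'
#' @param signal A [measured_signal()] or numeric vector.
#' @param snr_db Target SNR in dB (power ratio); `Inf` returns the signal
#'   unchanged.
#' @param seed Optional RNG seed for reproducible noise.
#' @param fs Sampling rate, Hz (used when `signal` is a bare vector).
#' @return A `measured_signal` with noise added.
#' @export
add_noise <- function(signal, snr_db, seed = NULL, fs = NULL) {
  if (inherits(signal, "measured_signal")) {
    s <- signal$samples; fs <- signal$fs; pe <- signal$pulse_energy
  } else {
    s <- as.numeric(signal); pe <- 1.0
    if (is.null(fs)) stop("fs required for a bare numeric signal", call. = FALSE)
  }
  if (!is.finite(snr_db)) return(measured_signal(s, fs, pe))
  p <- mean(s^2)
  if (p == 0) stop("zero-power signal with finite snr_db", call. = FALSE)
  sd_n <- sqrt(p * 10^(-snr_db / 10))
  noise <- with_seed(seed, stats::rnorm(length(s), sd = sd_n))
  measured_signal(s + noise, fs, pe)
}

#' Correct a trace for laser pulse-energy fluctuation
#'
#' Rescales a shot to a reference pulse energy using the photodiode
#' reading of the shot's actual energy, `samples * E_ref / E_meas`.
#'
#' @param y A [measured_signal()].
#' @param E_meas Measured pulse energy of the shot (must be > 0).
#' @param E_ref Reference pulse energy (default 1).
#' @return A `measured_signal` normalized to `E_ref`.
#' @export
pulse_energy_correct <- function(y, E_meas, E_ref = 1.0) {
  if (!(E_meas > 0)) stop("E_meas must be positive", call. = FALSE)
  measured_signal(y$samples * (E_ref / E_meas), y$fs, pulse_energy = E_ref)
}

#' Normalize dictionary columns to unit Euclidean norm
#'
#' @param K A `calibration_dictionary`.
#' @return The dictionary with unit-norm columns and the original norms
#'   cached in `column_norms` (zero columns are left untouched and keep
#'   norm 0).
#' @export
normalize_columns <- function(K) {
  if (isTRUE(K$normalized)) return(K)
  cn <- sqrt(colSums(K$columns^2))
  scale <- ifelse(cn > 0, cn, 1)
  K$columns <- sweep(K$columns, 2, scale, "/")
  K$column_norms <- cn
  K$normalized <- TRUE
  K
}
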