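#' Acoustic system parameters
#'
#' Bundles the physical constants of the detection chain: sound speeds in
#' the coupling water and in the fused-silica relay pipe, the transducer
#' center frequency and -6 dB fractional bandwidth, the pipe geometry, and
#' the digitizer settings. All quantities are SI (m, s, Hz); interfaces
#' that deal in voxel coordinates use millimetres and say so.
#'
#' @param v_water Sound speed in water, m/s.
#' @param v_pipe Sound speed in the fused-silica pipe, m/s. Must exceed
#'   `v_water` for a total-internal-reflection regime to exist.
#' @param f_c Transducer center frequency, Hz.
#' @param frac_bw_6db -6 dB fractional bandwidth of the transducer power
#'   spectrum (full width / center frequency), dimensionless in (0, 2).
#' @param pipe_length Length of the relay pipe, m.
#' @param pipe_radius Radius of the pipe entrance aperture, m.
#' @param fs Sampling rate of the digitizer, Hz. Must satisfy
#'   `fs > 2 * f_c * (1 + frac_bw_6db / 2)` so the transducer band is
#'   sampled above Nyquist.
#' @param n_samples Record length in samples.
#'
#' @return An object of class `acoustic_params`.
#' @export
#' @examples
#' p <- acoustic_params()
#' critical_angle(p) * 180 / pi  # 14.73 degrees
acoustic_params <- function(v_water = 1500, v_pipe = 5900,
                            f_c = 1e6, frac_bw_6db = 0.8466,
                            pipe_length = 0.30, pipe_radius = 0.015,
                            fs = 20e6, n_samples = 4096) {
  stopifnot(is.numeric(v_water), is.numeric(v_pipe), is.numeric(f_c))
  if (!(v_water > 0 && v_pipe > v_water))
    stop("require 0 < v_water < v_pipe", call. = FALSE)
  if (!(frac_bw_6db > 0 && frac_bw_6db < 2))
    stop("frac_bw_6db must lie in (0, 2)", call. = FALSE)
  if (!(f_c > 0)) stop("f_c must be positive", call. = FALSE)
  if (!(fs > 2 * f_c * (1 + frac_bw_6db / 2)))
    stop("fs must exceed twice the upper band edge 2*f_c*(1 + frac_bw_6db/2)",
         call. = FALSE)
  if (!(pipe_length > 0 && pipe_radius > 0))
    stop("pipe geometry must be positive", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("n_samples must be >= 1", call. = FALSE)
  structure(
    list(v_water = v_water, v_pipe = v_pipe, f_c = f_c,
         frac_bw_6db = frac_bw_6db, pipe_length = pipe_length,
         pipe_radius = pipe_radius, fs = fs, n_samples = n_samples),
    class = "acoustic_params")
}

#' @export
print.acoustic_params <- function(x, ...) {
  cat("<acoustic_params>\n")
  cat(sprintf("  v_water %g m/s, v_pipe %g m/s\n", x$v_water, x$v_pipe))
  cat(sprintf("  f_c %g MHz, -6 dB fractional bandwidth %.4g\n",
              x$f_c / 1e6, x$frac_bw_6db))
  cat(sprintf("  pipe %g cm long, %g cm aperture radius\n",
              x$pipe_length * 100, x$pipe_radius * 100))
  cat(sprintf("  fs %g MHz, %d samples (%.1f us record)\n",
              x$fs / 1e6, x$n_samples, x$n_samples / x$fs * 1e6))
  invisible(x)
}

#' A single-shot detector trace
#'
#' A time series recorded by the single-element transducer, with its
#' sampling rate and the relative laser pulse energy of the shot.
#'
#' @param samples Numeric vector of detector voltages (arbitrary units).
#' @param fs Sampling rate, Hz.
#' @param pulse_energy Relative pulse energy of the shot (default 1).
#' @return An object of class `measured_signal`.
#' @export
measured_signal <- function(samples, fs, pulse_energy = 1.0) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  stopifnot(fs > 0, pulse_energy > 0 || pulse_energy == 0)
  structure(list(samples = samples, fs = fs, pulse_energy = pulse_energy),
            class = "measured_signal")
}

#' @export
print.measured_signal <- function(x, ...) {
  cat(sprintf("<measured_signal> %d samples at %g MHz (%.1f us), pulse energy %g\n",
              length(x$samples), x$fs / 1e6,
              length(x$samples) / x$fs * 1e6, x$pulse_energy))
  invisible(x)
}

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Derive a 32-bit sub-seed from (seed, k); injective in k for k < 2^31-1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k)) %% 2147483647)
}
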