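#' Synthesize a single-shot measurement
#'
#' The measurement model: the detector trace is the linear superposition
#' of the calibration columns weighted by the voxel intensities,
#' `y = K x`, optionally degraded by detector-referred white noise.
#'
#' @param K A `calibration_dictionary`.
#' @param x A [volume_image()] or numeric vector of length N.
#' @param snr_db SNR of the added noise in dB; `Inf` (default) for a
#'   noiseless trace.
#' @param seed Optional RNG seed for the noise.
#' @return A [measured_signal()].
#' @export
synthesize <- function(K, x, snr_db = Inf, seed = NULL) {
  xv <- if (inherits(x, "volume_image")) x$values else as.numeric(x)
  if (length(xv) != ncol(K$columns))
    stop("image length does not match dictionary column count", call. = FALSE)
  if (!all(is.finite(xv))) stop("x must be finite", call. = FALSE)
  y0 <- as.vector(K$columns %*% xv)
  sig <- measured_signal(y0, K$params$fs)
  if (!is.finite(snr_db)) return(sig)
  add_noise(sig, snr_db, seed = seed)
}

#' Data-fidelity term of the inverse problem
#'
#' `0.5 * ||y - K x||^2` in the Euclidean norm.
#'
#' @param y A [measured_signal()] or numeric trace.
#' @param K A `calibration_dictionary`.
#' @param x A [volume_image()] or numeric vector.
#' @return Scalar residual.
#' @export
residual_norm <- function(y, K, x) {
  yv <- if (inherits(y, "measured_signal")) y$samples else as.numeric(y)
  xv <- if (inherits(x, "volume_image")) x$values else as.numeric(x)
  if (length(yv) != nrow(K$columns) || length(xv) != ncol(K$columns))
    stop("dimension mismatch between y, K and x", call. = FALSE)
  r <- yv - as.vector(K$columns %*% xv)
  0.5 * sum(r^2)
}
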