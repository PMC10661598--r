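measured_bandwidth <- function(w, fs) {
  L <- 2^16
  S <- Mod(stats::fft(c(w, numeric(L - length(w)))))^2
  f <- (0:(L - 1)) * fs / L
  keep <- f < fs / 2
  S <- S[keep]; f <- f[keep]
  pk <- which.max(S)
  half <- S[pk] * 10^-0.6
  lo <- stats::approx(S[1:pk], f[1:pk], xout = half)$y
  hi <- stats::approx(rev(S[pk:length(S)]), rev(f[pk:length(S)]), xout = half)$y
  list(f_peak = f[pk], frac_bw = (hi - lo) / f[pk])
}

test_that("transducer pulse has the specified center frequency and bandwidth", {
  p <- acoustic_params()
  w <- transducer_pulse(p)
  expect_equal(sum(w^2), 1, tolerance = 1e-12)
  m <- measured_bandwidth(w, p$fs)
  expect_lt(abs(m$f_peak - 1e6), p$fs / 2^16 * 2)   # within a fine bin
  expect_lt(abs(m$frac_bw - 0.8466) / 0.8466, 0.02)
})

test_that("undersampled configurations are rejected", {
  expect_error(acoustic_params(fs = 2.5e6), "Nyquist|band")
})

test_that("critical angle follows Snell's law", {
  p <- acoustic_params()
  expect_equal(critical_angle(p) * 180 / pi, 14.73, tolerance = 0.005 / 14.73)
  expect_equal(critical_angle(acoustic_params(v_water = 2950)) * 180 / pi, 30)
  p_bad <- p; p_bad$v_water <- p$v_pipe
  expect_error(critical_angle(p_bad), "v_water")
  # near-equal speeds approach grazing incidence
  expect_gt(critical_angle(acoustic_params(v_water = 5899.99)) * 180 / pi, 89)
})

test_that("time of flight is water path plus fixed pipe transit", {
  p <- acoustic_params()
  expect_equal(time_of_flight(c(0, 0, 15), p) * 1e6, 60.847, tolerance = 1e-4)
  expect_equal(time_of_flight(c(0, 0, 0), p) * 1e6, 50.847, tolerance = 1e-4)
  expect_gt(time_of_flight(c(0, 0, 30), p), time_of_flight(c(0, 0, 15), p))
  expect_error(time_of_flight(c(0, 0, -1), p), "behind")
})

test_that("aperture weight matches the spherical-cap formula on axis", {
  p <- acoustic_params()
  thc <- critical_angle(p)
  # disk subtends more than the critical cone: full critical-angle cap
  expect_equal(aperture_weight(c(0, 0, 20), p), (1 - cos(thc)) / 2,
               tolerance = 1e-4)
  # disk subtending half the critical angle: strictly smaller weight
  d_half <- p$pipe_radius * 1e3 / tan(thc / 2)
  expect_lt(aperture_weight(c(0, 0, d_half), p), (1 - cos(thc)) / 2)
  expect_equal(aperture_weight(c(0, 0, d_half), p), (1 - cos(thc / 2)) / 2,
               tolerance = 1e-3)
  # far off-axis voxels see no accepted rays
  expect_equal(aperture_weight(c(100, 0, 20), p), 0)
  expect_error(aperture_weight(c(0, 0, 0), p), "positive distance")
})

test_that("aperture weight is nonincreasing in distance on axis", {
  p <- acoustic_params()
  d <- seq(20, 200, by = 20)
  w <- vapply(d, function(z) aperture_weight(c(0, 0, z), p), 0)
  expect_true(all(diff(w) <= 1e-12))
})

test_that("codas are deterministic, near-orthogonal and unit-normalized", {
  p <- test_params()
  enc <- encoder_config(coda_len = 2000L, coda_decay_tau = 100e-6, seed = 5)
  a <- scramble_coda(3, enc, p)
  expect_identical(a, scramble_coda(3, enc, p))
  expect_equal(sum(a^2), 1, tolerance = 1e-12)
  r <- vapply(seq_len(100), function(k) {
    stats::cor(scramble_coda(2 * k, enc, p), scramble_coda(2 * k + 1, enc, p))
  }, 0)
  expect_lt(max(abs(r)), 0.1)
  expect_identical(scramble_coda(0, encoder_config(coda_len = 1L), p), 1.0)
})

test_that("degenerate dictionary reduces to delay-and-scale", {
  g <- test_grid(c(3L, 3L, 2L))
  p <- test_params()
  K <- delay_scale_dictionary(g)
  pulse <- transducer_pulse(p)
  for (i in c(0L, 4L, g$n - 1L)) {
    cm <- voxel_center(g, i)
    shift <- round(time_of_flight(cm, p) * p$fs)
    expected <- numeric(p$n_samples)
    expected[shift + seq_along(pulse)] <- aperture_weight(cm, p) * pulse
    expect_equal(K$columns[, i + 1L], expected, tolerance = 1e-12)
    # cross-correlation with the pulse peaks exactly at the delay lag
    lags <- 0:(p$n_samples - length(pulse))
    cc <- vapply(lags, function(s) sum(pulse * K$columns[s + seq_along(pulse), i + 1L]), 0)
    expect_identical(lags[which.max(cc)], as.integer(shift))
  }
})

test_that("voxels at equal water distance share arrival but not waveform", {
  g <- test_grid(c(5L, 5L, 2L))
  K <- build_dictionary(g, test_params(),
                        test_encoder(lateral_fwhm_mm = 0, calib_snr_db = Inf))
  # (0,4) and (4,4) in x are mirror images about the axis: same distance
  i1 <- linear_index(g, c(0, 2, 0)); i2 <- linear_index(g, c(4, 2, 0))
  c1 <- K$columns[, i1 + 1L]; c2 <- K$columns[, i2 + 1L]
  expect_identical(which(c1 != 0)[1], which(c2 != 0)[1])
  expect_gt(sum(abs(c1 - c2)), 0.1)
})

test_that("two-shot averaging halves the calibration noise variance", {
  g <- test_grid(c(2L, 2L, 1L), standoff = 5)  # short record suffices
  p <- test_params(512L)
  base <- function(n_avg, snr, seed)
    build_dictionary(g, p, test_encoder(seed = seed, coda_len = 50L,
                                        lateral_fwhm_mm = 0,
                                        calib_snr_db = snr, n_avg = n_avg))
  v <- vapply(1:200, function(s) {
    # matched noiseless build: same seed, hence identical codas
    K0 <- base(1L, Inf, s)$columns
    c(mean((base(1L, 20, s)$columns - K0)^2),
      mean((base(2L, 20, s)$columns - K0)^2))
  }, c(0, 0))
  ratio <- mean(v[2, ]) / mean(v[1, ])
  expect_equal(ratio, 0.5, tolerance = 0.08)
})

test_that("lateral mixing is normalized, local and correlation-increasing", {
  g <- test_grid(c(5L, 5L, 1L))
  K_raw <- build_dictionary(g, test_params(),
                            test_encoder(lateral_fwhm_mm = 0,
                                         calib_snr_db = Inf))$columns
  expect_identical(lateral_mix(K_raw, g, 0), K_raw)
  # weights sum to one: a dictionary of identical columns is invariant
  Kc <- matrix(rep(K_raw[, 1], g$n), ncol = g$n)
  expect_equal(lateral_mix(Kc, g, 2.5), Kc, tolerance = 1e-12)
  K_mix <- lateral_mix(K_raw, g, 2.5)
  i <- linear_index(g, c(2, 2, 0)) + 1L
  j <- linear_index(g, c(3, 2, 0)) + 1L
  expect_gt(stats::cor(K_mix[, i], K_mix[, j]),
            stats::cor(K_raw[, i], K_raw[, j]))
})

test_that("dictionary columns are incoherent beyond one lateral FWHM", {
  # default encoder; 1 mm lateral pitch so the grid spans well beyond
  # the mixing kernel
  g <- test_grid(c(7L, 7L, 5L), inc = c(1, 1, 0.3))
  K <- normalize_columns(build_dictionary(g, acoustic_params(),
                                          encoder_config(seed = 42)))
  G <- crossprod(K$columns)
  cn <- voxel_centers(g)
  D <- as.matrix(stats::dist(cn))
  sep <- D > 2.5
  expect_gt(sum(sep), 0)
  expect_lt(max(abs(G[sep])), 0.5)
})

test_that("dictionary build is reproducible from its configuration", {
  a <- build_dictionary(test_grid(c(3L, 3L, 2L)), test_params(), test_encoder())
  b <- build_dictionary(test_grid(c(3L, 3L, 2L)), test_params(), test_encoder())
  expect_identical(a$columns, b$columns)
})

test_that("record too short for a voxel's response is reported by voxel", {
  g <- test_grid(c(2L, 2L, 1L))
  expect_error(build_dictionary(g, test_params(256L), test_encoder()),
               "exceeds the record length")
})

test_that("added noise realizes the requested SNR", {
  p <- test_params()
  s <- measured_signal(sin(2 * pi * (1:4096) / 40), fs = p$fs)
  expect_identical(add_noise(s, Inf)$samples, s$samples)
  snr <- vapply(1:100, function(k) {
    n <- add_noise(s, 20, seed = k)$samples - s$samples
    10 * log10(mean(s$samples^2) / mean(n^2))
  }, 0)
  expect_lt(abs(mean(snr) - 20), 0.5)
  expect_identical(add_noise(s, 20, seed = 9)$samples,
                   add_noise(s, 20, seed = 9)$samples)
  expect_error(add_noise(measured_signal(numeric(64), p$fs), 20), "zero-power")
})

test_that("pulse-energy correction rescales to the reference energy", {
  y <- measured_signal(c(1, -2, 3), fs = 1e6)
  expect_equal(pulse_energy_correct(y, 1, 1)$samples, y$samples)
  half <- pulse_energy_correct(y, 2, 1)
  expect_equal(half$samples, y$samples / 2)
  expect_equal(half$pulse_energy, 1)
  expect_error(pulse_energy_correct(y, 0), "positive")
})

test_that("column normalization caches norms and is idempotent", {
  K <- small_dictionary()
  Kn <- normalize_columns(K)
  expect_equal(max(abs(colSums(Kn$columns^2) - 1)), 0, tolerance = 1e-9)
  expect_equal(Kn$column_norms, sqrt(colSums(K$columns^2)))
  expect_identical(normalize_columns(Kn)$columns, Kn$columns)
})
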