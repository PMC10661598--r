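# Shared small-scale fixtures. Tests that exercise the dictionary and
# solver use a short relay (5 cm pipe, 1024-sample record) and small
# grids so each build takes well under a second; the physics is
# identical to the full-scale defaults.

test_params <- function(n_samples = 1024L) {
  acoustic_params(pipe_length = 0.05, n_samples = n_samples)
}

test_grid <- function(counts = c(5L, 5L, 4L), standoff = 8,
                      inc = c(0.5, 0.5, 0.3)) {
  ext <- (counts - 1L) * inc
  ext[ext == 0] <- inc[ext == 0] / 2  # single-voxel axes
  make_grid(ext, inc, origin_mm = c(-(counts[1] - 1L) * inc[1] / 2,
                                    -(counts[2] - 1L) * inc[2] / 2, standoff))
}

test_encoder <- function(seed = 42L, coda_len = 200L, lateral_fwhm_mm = 2.5,
                         calib_snr_db = 40, n_avg = 2L) {
  encoder_config(coda_len = coda_len, coda_decay_tau = 20e-6,
                 lateral_fwhm_mm = lateral_fwhm_mm,
                 calib_snr_db = calib_snr_db, n_avg = n_avg, seed = seed)
}

# memoised default small dictionary (built once per test file)
.fixture_env <- new.env(parent = emptyenv())
small_dictionary <- function() {
  if (is.null(.fixture_env$K))
    .fixture_env$K <- build_dictionary(test_grid(), test_params(),
                                       test_encoder())
  .fixture_env$K
}

# noiseless, unmixed, coda-free dictionary: pure delay-and-scale model
delay_scale_dictionary <- function(grid = test_grid()) {
  build_dictionary(grid, test_params(),
                   test_encoder(coda_len = 0L, lateral_fwhm_mm = 0,
                                calib_snr_db = Inf, n_avg = 1L))
}
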