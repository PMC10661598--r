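test_that("FWHM of analytic profiles matches closed forms", {
  x <- seq(-5, 5, by = 0.1)
  gauss <- exp(-x^2 / 2)  # sigma = 1 mm
  expect_equal(fwhm(gauss, 0.1), 2 * sqrt(2 * log(2)),
               tolerance = 0.02)

  tri <- pmax(0, 1 - abs(x) / 2)  # half-width 2 mm
  expect_equal(fwhm(tri, 0.1), 2, tolerance = 1e-9)

  spike <- c(0, 0, 1, 0, 0)
  expect_equal(fwhm(spike, 0.3), 0.3)
  expect_equal(fwhm(1, 0.25), 0.25)  # single-sample profile convention

  expect_error(fwhm(numeric(5), 0.1), "all-zero")
  expect_error(fwhm(c(1, 2, 2, 1), 0.1), "unique")
  expect_error(fwhm(c(0.9, 1, 0.9), 0.1), "below half")
})

test_that("centroid averages the thresholded object-pixel coordinates", {
  g <- default_grid("desk")
  d <- disk_phantom(c(0.5, -0.5, 21.5), 3, 1, g)
  expect_equal(centroid(d), c(0.5, -0.5, 21.5), tolerance = 0.25)

  single <- point_target(c(1, 1, 20.9), g)
  expect_equal(centroid(single), c(1, 1, 20.9), tolerance = 1e-12)

  v <- numeric(g$n)
  v[linear_index(g, c(7, 7, 0)) + 1] <- 1
  v[linear_index(g, c(7, 7, 2)) + 1] <- 1
  expect_equal(centroid(volume_image(v, g))[3], 20.3)  # mean of 20, 20.6

  # sub-threshold voxels are excluded
  v[linear_index(g, c(0, 0, 0)) + 1] <- 0.4
  expect_equal(centroid(volume_image(v, g))[1], 0)
  expect_error(centroid(volume_image(numeric(g$n), g)), "empty")
})

test_that("two-point criterion detects a Rayleigh-like dip", {
  g <- default_grid("desk")
  v <- numeric(g$n)
  p1 <- c(-2, 0, 21.5); p2 <- c(2, 0, 21.5)
  v[point_target(p1, g)$values == 1] <- 1
  v[point_target(p2, g)$values == 1] <- 0.9
  im <- volume_image(v, g)
  expect_true(two_point_resolved(im, p1, p2))
  expect_false(two_point_resolved(im, p1, p1))
  # fill the midpoint above the dip threshold: no longer resolved
  v[point_target(c(0, 0, 21.5), g)$values == 1] <- 0.8
  expect_false(two_point_resolved(volume_image(v, g), p1, p2))
})

test_that("image correlation behaves as a Pearson fidelity metric", {
  set.seed(13)
  g <- test_grid()
  a <- volume_image(runif(g$n), g)
  expect_equal(image_correlation(a, a), 1)
  expect_equal(image_correlation(a, volume_image(-a$values, g)), -1)
  expect_equal(image_correlation(a, volume_image(a$values + 5, g)), 1)
  expect_error(image_correlation(a, volume_image(rep(1, g$n), g)), "variance")
})

test_that("zero-magnitude drift returns the dictionary unchanged", {
  K <- small_dictionary()
  expect_identical(drift_perturb(K, 0, 0, 0, seed = 1)$columns, K$columns)
})

test_that("gain drift preserves column norms within the Gaussian bound", {
  K <- small_dictionary()
  f <- 0.03
  Kp <- drift_perturb(K, 0, f, 0, seed = 2)
  rel <- abs(sqrt(colSums(Kp$columns^2)) / sqrt(colSums(K$columns^2)) - 1)
  expect_gt(mean(rel <= 3 * f), 0.99)
})

test_that("reconstruction fidelity degrades with calibration delay jitter", {
  K <- small_dictionary()
  g <- K$grid
  ph <- disk_phantom(c(0, 0, g$origin_mm[3] + 0.6), 1.5, 0.6, g)
  y <- synthesize(K, ph)
  cfg <- recon_config(lam = 1e-6, max_iter = 60)
  r <- vapply(c(0, 50, 200, 1000), function(j) {
    Kp <- drift_perturb(K, j, 0, 0, seed = 31)
    image_correlation(twist_reconstruct(y, Kp, cfg)$image, ph)
  }, 0)
  # zero perturbation reproduces the unperturbed fidelity exactly
  expect_identical(r[1],
                   image_correlation(twist_reconstruct(y, K, cfg)$image, ph))
  expect_true(all(diff(r) <= 0.02))  # monotone decay within noise
  expect_lt(r[4], r[1] - 0.1)
})

test_that("sub-sample delay jitter shifts columns without reshaping them", {
  K <- small_dictionary()
  Kp <- drift_perturb(K, 500, 0, 0, seed = 5)  # 500 ns ~ 10 samples max
  expect_equal(sqrt(colSums(Kp$columns^2)), sqrt(colSums(K$columns^2)),
               tolerance = 1e-6)
  expect_gt(mean(abs(Kp$columns - K$columns)), 0)
})

test_that("tracking a stationary object is unbiased", {
  # unmixed encoder: isolates the tracking pipeline from lateral blur
  K <- build_dictionary(test_grid(), test_params(),
                        test_encoder(lateral_fwhm_mm = 0))
  g <- K$grid
  ctr <- c(0, 0, g$origin_mm[3] + 0.6)
  traj <- matrix(rep(ctr, each = 3), 3, 3)
  tr <- track(K, traj, list(diameter_mm = 0, thickness_mm = 0),
              recon_config(lam = 1e-6, max_iter = 60), snr_db = Inf)
  expect_true(all(abs(tr$per_axis_mean) < 0.1))
  expect_true(all(tr$per_axis_sd < 0.1))
  expect_identical(nrow(tr$est_centers), nrow(tr$true_centers))
})

test_that("noiseless tracking frames are independent of ordering", {
  K <- small_dictionary()
  g <- K$grid
  z0 <- g$origin_mm[3]
  traj <- spiral_trajectory(c(0, 0), 0.5, z0, z0 + 0.9, 1, 3, g)
  cfg <- recon_config(lam = 1e-6, max_iter = 40)
  spec <- list(diameter_mm = 1, thickness_mm = 0.6)
  fwd <- track(K, traj, spec, cfg, snr_db = Inf)
  rev_ <- track(K, traj[3:1, ], spec, cfg, snr_db = Inf)
  expect_equal(rev_$est_centers, fwd$est_centers[3:1, ], tolerance = 1e-12)
})

test_that("point-spread resolution is deterministic and axially finer", {
  K <- small_dictionary()
  cfg <- recon_config(lam = 1e-6, max_iter = 60)
  lat <- measure_resolution(K, cfg, "lateral")
  axi <- measure_resolution(K, cfg, "axial")
  expect_identical(lat, measure_resolution(K, cfg, "lateral"))
  expect_lt(axi, lat)
})
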