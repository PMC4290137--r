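test_that("the default configuration carries the reference parameter set", {
  cfg <- seg_config()
  expect_equal(cfg$dt, 4.0)
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$beta, 0.5)
  expect_equal(cfg$sigma, 3.0)
  expect_equal(cfg$eps, 1.0)
  expect_equal(cfg$k, 0.9)
  expect_null(cfg$global_mu)
  expect_error(seg_config(dt = -1), "positive")
  expect_warning(seg_config(k = 0.2), "range")
  expect_warning(seg_config(beta = 10), "unstable")
})

test_that("configurations round-trip through the flat key-value format", {
  cfg <- seg_config(alpha = 0.02, sigma = 2.5, global_mu = 137,
                    max_iters = 42L, normalize = TRUE)
  p <- tempfile(fileext = ".cfg")
  write_seg_config(cfg, p)
  back <- read_seg_config(p)
  for (nm in setdiff(names(cfg), "diffusion"))
    expect_equal(back[[nm]], cfg[[nm]], info = nm)
})

test_that("seed initialization produces the signed distance of the seed union", {
  phi <- initialize_phi(c(30, 30, 30), seed_ball(c(15, 15, 15), 5))
  expect_true(phi$is_sdf)
  expect_lt(abs(phi$data[16, 16, 16] - 5), 0.6)
  surf <- abs(sphere_distance(c(30, 30, 30), c(15, 15, 15), 5)) < 0.3
  expect_lt(max(abs(phi$data[surf])), 0.8)

  # two disjoint balls: positive exactly inside either
  seeds <- seed_spec(seed_ball(c(8, 8, 8), 4), seed_ball(c(22, 22, 22), 4))
  phi2 <- initialize_phi(c(30, 30, 30), seeds)
  want <- ball_region(c(30, 30, 30), c(8, 8, 8), 4) |
    ball_region(c(30, 30, 30), c(22, 22, 22), 4)
  expect_identical(phi2$data >= 0, want)

  expect_error(initialize_phi(c(30, 30, 30), seed_ball(c(40, 15, 15), 3)),
               "outside")
  expect_error(initialize_phi(c(10, 10, 10),
                              seed_mask(binary_mask(array(1, c(10, 10, 10))))),
               "degenerate")
  expect_error(seed_spec(), "at least one")
})

test_that("seed order does not affect the initial field", {
  a <- seed_ball(c(8, 8, 8), 4); b <- seed_ball(c(20, 14, 20), 5)
  p1 <- initialize_phi(c(30, 30, 30), seed_spec(a, b))
  p2 <- initialize_phi(c(30, 30, 30), seed_spec(b, a))
  expect_identical(p1$data, p2$data)
})

test_that("mask extraction follows the phi >= 0 convention", {
  expect_equal(sum(extract_mask(array(-1, c(4, 4, 4)))$data), 0)
  phi <- initialize_phi(c(20, 20, 20), seed_ball(c(10, 10, 10), 6))
  count <- sum(extract_mask(phi)$data)
  expect_lt(abs(count - 4 / 3 * pi * 6^3), 0.1 * 4 / 3 * pi * 6^3)
  expect_identical(extract_mask(phi)$data >= 1,
                   ball_region(c(20, 20, 20), c(10, 10, 10), 6))
})

test_that("intensity normalization is an idempotent affine map to [0, 1]", {
  v <- image_volume(array(seq(0, 500, length.out = 27), c(3, 3, 3)))
  n <- normalize_intensity(v)
  expect_equal(range(n$data), c(0, 1))
  expect_equal(n$data[which(v$data == 250)], 0.5)
  expect_equal(normalize_intensity(n)$data, n$data, tolerance = 1e-12)
  expect_error(normalize_intensity(image_volume(array(5, c(3, 3, 3)))),
               "constant")
})

test_that("a uniformly positive region force grows the contour", {
  vol <- image_volume(array(300, c(24, 24, 24)))
  # seed well above the radius where curvature shrinkage balances the
  # region force, so the uniformly positive force dominates
  phi0 <- initialize_phi(c(24, 24, 24), seed_ball(c(12, 12, 12), 6))
  res <- evolve(vol, phi0, seg_config(max_iters = 15))
  # localized mu = 0.9 * 300 = 270 < 300 everywhere
  expect_true(all(diff(res$trace$interior_voxels) >= 0))
  n <- res$iterations
  expect_gt(res$trace$interior_voxels[n], res$trace$interior_voxels[1])
})

test_that("a bright ball on dark background is recovered almost exactly", {
  shape <- c(48, 48, 48)
  vol <- make_ball_volume(shape, c(23.5, 23.5, 23.5), 12)
  truth <- binary_mask(ball_region(shape, c(23.5, 23.5, 23.5), 12))
  phi0 <- initialize_phi(shape, seed_ball(c(23, 23, 23), 4))
  res <- evolve(vol, phi0, seg_config(max_iters = 200))
  expect_lte(res$iterations, 200)
  expect_gte(dice_coefficient(truth, res$mask), 0.95)
})

test_that("a global threshold above all intensities collapses the contour", {
  shape <- c(32, 32, 32)
  vol <- make_ball_volume(shape, c(15.5, 15.5, 15.5), 8)
  phi0 <- initialize_phi(shape, seed_ball(c(15, 15, 15), 4))
  expect_error(evolve(vol, phi0, seg_config(global_mu = 600)),
               class = "lhvessel_degenerate_interface")
})

test_that("on a constant image the localized model equals the global baseline", {
  shape <- c(24, 24, 24)
  vol <- image_volume(array(320, shape))
  for (iters in c(1, 4, 9)) {
    p1 <- initialize_phi(shape, seed_ball(c(12, 12, 12), 5))
    r_loc <- evolve(vol, p1, seg_config(max_iters = iters, record_phi = TRUE))
    p2 <- initialize_phi(shape, seed_ball(c(12, 12, 12), 5))
    r_glb <- evolve(vol, p2, seg_config(max_iters = iters, record_phi = TRUE,
                                        global_mu = 0.9 * 320))
    expect_identical(r_loc$iterations, r_glb$iterations)
    for (i in seq_len(r_loc$iterations))
      expect_equal(r_loc$snapshots[[i]], r_glb$snapshots[[i]],
                   tolerance = 1e-12)
  }
})

test_that("evolution is deterministic", {
  shape <- c(32, 32, 32)
  set.seed(31)
  vol <- image_volume(array(runif(prod(shape), 0, 500), shape))
  run <- function() {
    phi0 <- initialize_phi(shape, seed_ball(c(16, 16, 16), 6))
    evolve(vol, phi0, seg_config(max_iters = 20))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$phi$data, r2$phi$data)
  expect_identical(r1$mask$data, r2$mask$data)
  expect_identical(r1$trace, r2$trace)
})

test_that("raising a voxel's intensity never lowers its region-updated phi", {
  shape <- c(20, 20, 20)
  set.seed(32)
  base <- array(runif(prod(shape), 0, 400), shape)
  bumped <- base
  bumped[9, 11, 10] <- bumped[9, 11, 10] + 150
  cfg <- seg_config(max_iters = 1, record_phi = TRUE, global_mu = 200)
  p1 <- initialize_phi(shape, seed_ball(c(9, 9, 9), 5))
  r1 <- evolve(image_volume(base), p1, cfg)
  p2 <- initialize_phi(shape, seed_ball(c(9, 9, 9), 5))
  r2 <- evolve(image_volume(bumped), p2, cfg)
  # after one full iteration the bumped voxel's field value cannot be lower
  # than in the baseline run by more than the edge-step's influence; check
  # the region update directly instead via the exposed kernels
  phi <- initialize_phi(shape, seed_ball(c(9, 9, 9), 5))$data
  mu <- array(200, shape)
  up1 <- phi + 4 * 0.01 * smoothed_dirac(phi, 1) * (base - mu)
  up2 <- phi + 4 * 0.01 * smoothed_dirac(phi, 1) * (bumped - mu)
  expect_gt(up2[9, 11, 10], up1[9, 11, 10])
  expect_equal(up2[-(9 + 20 * 10 + 400 * 9)], up1[-(9 + 20 * 10 + 400 * 9)])
})

test_that("the evolution trace records one row per completed iteration", {
  vol <- make_ball_volume(c(24, 24, 24), c(11.5, 11.5, 11.5), 7)
  phi0 <- initialize_phi(c(24, 24, 24), seed_ball(c(11, 11, 11), 3))
  res <- evolve(vol, phi0, seg_config(max_iters = 12))
  expect_equal(res$trace$iteration, seq_len(res$iterations))
  expect_true(all(res$trace$interior_voxels >= 0))
  expect_true(all(res$trace$changed_voxels >= 0))
})
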