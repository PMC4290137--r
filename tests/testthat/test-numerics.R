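test_that("smoothed Heaviside matches its closed form and is monotone", {
  for (eps in c(0.5, 1, 2)) {
    expect_equal(smoothed_heaviside(0, eps), 0.5)
    expect_equal(smoothed_heaviside(eps, eps), 0.75)  # atan(1) = pi/4
    s <- seq(-10 * eps, 10 * eps, length.out = 401)
    direct <- 0.5 * (1 + (2 / pi) * atan(s / eps))
    expect_equal(smoothed_heaviside(s, eps), direct)
    expect_true(all(diff(smoothed_heaviside(s, eps)) > 0))
    expect_equal(smoothed_heaviside(s, eps) + smoothed_heaviside(-s, eps),
                 rep(1, length(s)))
  }
  expect_error(smoothed_heaviside(0, 0), "positive")
  expect_error(smoothed_dirac(0, -1), "positive")
})

test_that("smoothed Dirac is even, integrates to one, and is the Heaviside derivative", {
  expect_equal(smoothed_dirac(0, 1), 1 / pi)
  s <- seq(-5, 5, length.out = 101)
  for (eps in c(0.5, 1, 2)) {
    expect_equal(smoothed_dirac(s, eps), smoothed_dirac(-s, eps))
    expect_equal(max(smoothed_dirac(s, eps)), 1 / (pi * eps))
    # quadrature over [-1e4 eps, 1e4 eps]
    q <- stats::integrate(smoothed_dirac, -1e4 * eps, 1e4 * eps, eps = eps,
                          rel.tol = 1e-10, subdivisions = 1000L)
    expect_lt(abs(q$value - 1), 1e-3)
    # numerical derivative of the Heaviside at step 1e-4 * eps
    h <- 1e-4 * eps
    deriv <- (smoothed_heaviside(s + h, eps) -
                smoothed_heaviside(s - h, eps)) / (2 * h)
    expect_equal(deriv, smoothed_dirac(s, eps), tolerance = 1e-6)
  }
})

test_that("edge indicator is 1 on flat volumes and responds to steps", {
  flat <- image_volume(array(42, c(6, 6, 6)))
  expect_equal(edge_indicator(flat)$data, array(1, c(6, 6, 6)))

  # one-voxel step of height delta along x, no smoothing: central difference
  # at the two voxels adjacent to the step sees delta/2
  delta <- 10
  step <- array(0, c(8, 5, 5)); step[5:8, , ] <- delta
  g <- edge_indicator(image_volume(step), c = 1, sigma_edge = 0)$data
  expect_equal(g[4, 3, 3], 1 / (1 + (delta / 2)^2))
  expect_equal(g[5, 3, 3], 1 / (1 + (delta / 2)^2))
  expect_equal(g[2, 3, 3], 1)

  set.seed(21)
  noisy <- image_volume(array(rnorm(1000), c(10, 10, 10)))
  g1 <- edge_indicator(noisy, c = 1)$data
  g2 <- edge_indicator(noisy, c = 2)$data
  expect_true(all(g2 <= g1))
  expect_true(all(g1 > 0 & g1 <= 1))
  expect_error(edge_indicator(noisy, c = 0), "positive")
})

test_that("local threshold map is the k-scaled Gaussian local mean", {
  const <- image_volume(array(300, c(12, 12, 12)))
  expect_equal(local_threshold_map(const, sigma = 3, k = 0.9)$data,
               array(270, c(12, 12, 12)))

  # impulse response equals the discretized Gaussian kernel
  sigma <- 2
  imp <- array(0, c(33, 33, 33)); imp[17, 17, 17] <- 1
  mu <- local_threshold_map(image_volume(imp), sigma = sigma, k = 1)$data
  expect_equal(max(mu), mu[17, 17, 17])
  expect_equal(mu[17, 17, 17], (2 * pi * sigma^2)^(-3 / 2), tolerance = 0.02)
  off <- mu[17 + 3, 17 + 2, 17 - 1]
  expect_equal(off, (2 * pi * sigma^2)^(-3 / 2) * exp(-(9 + 4 + 1) /
                                                        (2 * sigma^2)),
               tolerance = 0.02)

  set.seed(22)
  v <- image_volume(array(runif(512, 0, 500), c(8, 8, 8)))
  expect_equal(local_threshold_map(v, k = 0.5)$data,
               (5 / 9) * local_threshold_map(v, k = 0.9)$data)
  # commutes with intensity scaling
  v3 <- image_volume(3.7 * v$data)
  expect_equal(local_threshold_map(v3, k = 0.9)$data,
               3.7 * local_threshold_map(v, k = 0.9)$data)
  expect_warning(local_threshold_map(v, k = 0.3), "range")
  expect_error(local_threshold_map(v, sigma = 0), "positive")
})

test_that("threshold map values never exceed k times the local maximum", {
  set.seed(23)
  v <- image_volume(array(runif(16^3, 0, 500), c(16, 16, 16)))
  sigma <- 1.5; k <- 0.9
  mu <- local_threshold_map(v, sigma = sigma, k = k)$data
  rad <- ceiling(4 * sigma)
  for (idx in list(c(8, 8, 8), c(2, 15, 7), c(16, 1, 16))) {
    win <- v$data[max(1, idx[1] - rad):min(16, idx[1] + rad),
                  max(1, idx[2] - rad):min(16, idx[2] + rad),
                  max(1, idx[3] - rad):min(16, idx[3] + rad)]
    expect_lte(mu[idx[1], idx[2], idx[3]], k * max(win) + 1e-12)
  }
})

test_that("SDF reinitialization reproduces the distance to a sphere", {
  shape <- c(40, 40, 40)
  ind <- array(ifelse(ball_region(shape, c(19.5, 19.5, 19.5), 10), 1, -1),
               shape)
  phi <- reinitialize_sdf(ind)
  expect_true(phi$is_sdf)
  exact <- sphere_distance(shape, c(19.5, 19.5, 19.5), 10)
  expect_lt(max(abs(phi$data - exact)), 1)
  # signs preserved voxelwise
  expect_true(all(sign(phi$data) == sign(ind) | phi$data == 0))
})

test_that("SDF reinitialization is idempotent and keeps |grad phi| near 1", {
  shape <- c(40, 40, 40)
  ind <- array(ifelse(ball_region(shape, c(19.5, 19.5, 19.5), 10), 1, -1),
               shape)
  phi1 <- reinitialize_sdf(ind)
  phi2 <- reinitialize_sdf(phi1)
  expect_lt(max(abs(phi2$data - phi1$data)), 0.51)

  gr <- lhvessel:::.grad3(as.double(phi1$data), dim(phi1$data))
  mag <- sqrt(gr$gx^2 + gr$gy^2 + gr$gz^2)
  off <- abs(phi1$data) > 2
  frac <- mean(mag[off] >= 0.8 & mag[off] <= 1.2)
  expect_gte(frac, 0.95)

  expect_error(reinitialize_sdf(array(1, c(4, 4, 4))), "degenerate")
  expect_error(reinitialize_sdf(array(-2, c(4, 4, 4))), "degenerate")
})

test_that("reinitialization never moves the interface across a voxel", {
  shape <- c(30, 30, 30)
  ind <- array(ifelse(ball_region(shape, c(14.5, 14.5, 14.5), 8), 1, -1),
               shape)
  phi <- reinitialize_sdf(ind)
  again <- reinitialize_sdf(phi)
  flipped <- sign(again$data) != sign(phi$data)
  expect_true(all(abs(phi$data[flipped]) < 1))
})

test_that("edge-weighted divergence matches analytic and loop oracles", {
  # linear field, g = 1: divergence vanishes in the interior
  shape <- c(10, 10, 10)
  lin <- array(rep(seq_len(10), 100), shape)
  d <- edge_weighted_divergence(lin, array(1, shape))
  expect_equal(max(abs(d[2:9, 2:9, 2:9])), 0)

  # SDF of a ball, g = 1: div(grad phi) = -2 / |x| near the interface
  shape <- c(40, 40, 40)
  r <- 10
  phi <- -sphere_distance(shape, c(19.5, 19.5, 19.5), r)  # |x| - r form
  d <- edge_weighted_divergence(phi, array(1, shape))
  band <- abs(phi) < 1.5 & phi > 0  # just outside the surface
  expect_lt(abs(mean(d[band]) - 2 / r) / (2 / r), 0.15)

  set.seed(24)
  p <- array(rnorm(16^3), c(16, 16, 16))
  g <- array(runif(16^3, 0.2, 1), c(16, 16, 16))
  expect_lt(max(abs(edge_weighted_divergence(p, g) - naive_ewdiv(p, g))),
            1e-10)
  expect_error(edge_weighted_divergence(p, g[1:8, 1:8, 1:8]), "shape")
})
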