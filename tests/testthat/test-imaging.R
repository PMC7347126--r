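test_that("grayscale conversion is identity on 2D and convex on RGB", {
  g <- matrix(runif(20), 4, 5)
  expect_identical(to_grayscale(g), g)

  rgb0 <- array(0, dim = c(4, 5, 3))
  expect_true(all(to_grayscale(rgb0) == 0))

  rgbc <- array(0.37, dim = c(4, 5, 3))
  expect_equal(to_grayscale(rgbc), matrix(0.37, 4, 5), tolerance = 1e-12)

  expect_error(to_grayscale(array(0, dim = c(0, 0, 3))), "empty")
})

test_that("anisotropic smoothing conserves flat fields and matches direct convolution", {
  flat <- matrix(3.7, 12, 15)
  expect_equal(gaussian_smooth(flat, c(2, 3)), flat, tolerance = 1e-12)

  set.seed(1)
  f <- matrix(0, 15, 15); f[8, 8] <- 1; f <- f + matrix(runif(225), 15, 15)
  got <- gaussian_smooth(f, c(1.5, 0.8))
  want <- direct_gaussian_smooth(f, c(1.5, 0.8))
  expect_equal(got, want, tolerance = 1e-10)

  # transpose symmetry: (sx, sy) on f == t((sy, sx) on t(f))
  expect_equal(gaussian_smooth(f, c(1.5, 0.8)),
               t(gaussian_smooth(t(f), c(0.8, 1.5))), tolerance = 1e-12)

  expect_error(gaussian_smooth(matrix(c(1, NA), 2, 2), c(1, 1)), "finite")
})

test_that("ratio segmentation thresholds against the local background", {
  f <- matrix(runif(100, 1, 2), 10, 10)
  expect_true(!any(segment_clusters(f, f, 1.5)$grid))
  expect_true(all(segment_clusters(3 * f, f, 2)$grid))
  expect_error(segment_clusters(f, f, 1), "> 1")
  expect_error(segment_clusters(f, matrix(1, 2, 2), 1.5), "shape")

  # zero-background convention: occupied iff intensity > 0
  bg0 <- matrix(0, 3, 3)
  fr <- matrix(c(0, 1e-9, 5, 0, 0, 0, 2, 0, 0), 3, 3)
  expect_identical(segment_clusters(fr, bg0, 1.5)$grid, fr > 0)
})

test_that("segmentation of a planted Gaussian spot matches per-pixel enumeration", {
  n <- 41; s <- 3
  ctr <- (n + 1) / 2
  spot <- outer(seq_len(n), seq_len(n), function(i, j)
    10 * exp(-((i - ctr)^2 + (j - ctr)^2) / (2 * s^2)))
  frame <- 1 + spot
  bg <- matrix(1, n, n)
  got <- segment_clusters(frame, bg, 2)$grid
  want <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) want[i, j] <- frame[i, j] > 2
  expect_identical(got, want)
  expect_true(sum(got) > 0 && sum(got) < n * n)
})

test_that("cell geometry gives exact closed forms and scaling behaviour", {
  one <- matrix(TRUE, 1, 1)
  g <- cell_geometry(one, pixel_size = 1)
  expect_equal(g$area, 1)
  expect_equal(g$equivalent_diameter, 2 / sqrt(pi), tolerance = 1e-12)
  expect_gt(g$perimeter, 0)

  # rasterized disc of radius 50 px: equivalent diameter within 2% of 100
  n <- 111; ctr <- 56
  disc <- outer(seq_len(n), seq_len(n),
                function(i, j) (i - ctr)^2 + (j - ctr)^2 <= 50^2)
  gd <- cell_geometry(disc, 1)
  expect_equal(gd$equivalent_diameter, 100, tolerance = 0.02)
  expect_equal(gd$perimeter, pi * 100, tolerance = 0.05)

  # doubling the mask scale doubles the diameter, quadruples the area
  disc2 <- outer(seq_len(2 * n), seq_len(2 * n),
                 function(i, j) (i - 2 * ctr)^2 + (j - 2 * ctr)^2 <= 100^2)
  g2 <- cell_geometry(disc2, 1)
  expect_equal(g2$equivalent_diameter / gd$equivalent_diameter, 2,
               tolerance = 0.01)
  expect_equal(g2$area / gd$area, 4, tolerance = 0.02)

  expect_error(cell_geometry(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("frame stacks validate their invariants", {
  f <- list(matrix(1, 3, 3), matrix(2, 3, 3))
  expect_s3_class(frame_stack(f, c(0, 10), 0.1), "frame_stack")
  expect_error(frame_stack(f, c(10, 0), 0.1), "increasing")
  expect_error(frame_stack(list(matrix(1, 3, 3), matrix(1, 2, 3)),
                           c(0, 1), 0.1), "identical")
  expect_error(frame_stack(list(matrix(-1, 2, 2)), 0, 0.1), "non-negative")
  expect_error(frame_stack(f, c(0, 10), 0), "positive")
})

test_that("density series is zero on background-only frames and counts planted pixels", {
  cellm <- matrix(TRUE, 20, 20)
  geom <- cell_geometry(cellm, 1)
  flat <- lapply(1:5, function(i) matrix(5, 20, 20))
  st <- frame_stack(flat, seq(0, 40, 10), 1)
  ds <- density_timeseries(st, geom)
  expect_true(all(ds$density == 0))

  # one frame with a bright square of k pixels on flat background
  fr <- matrix(5, 20, 20); fr[9:11, 9:11] <- 500
  st2 <- frame_stack(c(flat, list(fr)), seq(0, 50, 10), 1)
  ds2 <- density_timeseries(st2, geom, threshold_ratio = 2, widths = c(5, 5))
  expect_equal(ds2$density[6], 9 / geom$perimeter, tolerance = 1e-12)
})

test_that("regime segmentation recovers the exponential-saturation curve", {
  fs <- 2.4; tau <- 100
  t <- seq(0, 1000, by = 2)
  y <- fs * (1 - exp(-t / tau))
  r <- segment_regimes(list(timestamps = t, density = y))
  # growth ends within sampling resolution of tau (steady mean slightly
  # below the asymptote shifts the crossing by < 3 samples)
  expect_lt(abs(r$growth_end - tau), 6)
  expect_lte(r$transient_end, r$growth_end)
  expect_equal(r$steady_mean, fs, tolerance = 0.01)
  expect_true(r$steady_band[1] <= r$steady_mean &&
              r$steady_mean <= r$steady_band[2])

  const <- rep(3.3, 20)
  rc <- segment_regimes(list(timestamps = seq(0, 190, 10), density = const))
  expect_equal(rc$transient_end, 0)
  expect_equal(rc$growth_end, 0)
  expect_equal(rc$steady_mean, 3.3)

  ramp <- seq(0, 1, length.out = 40)   # never stationary
  expect_error(segment_regimes(list(timestamps = seq_len(40), density = ramp)),
               "no steady state")
})

test_that("three-regime synthetic series yields change points within one interval", {
  set.seed(3)
  dt <- 10; t0 <- 60; tau <- 120
  t <- seq(0, 1200, by = dt)
  y <- ifelse(t > t0, 5 * (1 - exp(-(t - t0) / tau)), 0)
  y <- y * (1 + rnorm(length(t), 0, 0.01))
  r <- segment_regimes(list(timestamps = t, density = y))
  # transient threshold (5% of steady) crossed just after t0
  expect_lt(abs(r$transient_end - t0), 2 * dt)
  expect_lt(abs(r$growth_end - (t0 + tau)), 2 * dt)
})
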