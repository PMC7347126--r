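# small test configuration: 125 x 125 sites (L = 0.625 um at 5 nm spacing)
small_cfg <- function(...) {
  lattice_config(L = 0.625, grid_spacing = 5, duration = 1000, seed = 5, ...)
}

# enumerate the Euclidean disc of radius r (the oracle for affected zones)
disc_size <- function(r) {
  g <- expand.grid(-r:r, -r:r)
  sum(g[, 1]^2 + g[, 2]^2 <= r^2)
}

test_that("lattice geometry and initial state follow the configuration", {
  cfg <- lattice_config(L = 10, grid_spacing = 5)
  expect_equal(cfg$n_side, 2000L)               # 10 um at 5 nm spacing
  expect_equal(cfg$n_total, as.integer(0.1 * 2000^2))

  st <- init_lattice(small_cfg())
  expect_equal(surface_fraction(st), 0)         # empty membrane start
  expect_equal(st$internal_pool, st$n_total)
  expect_equal(st$time, 0)

  # same seed gives the same RNG stream (hot-spot layout and first draws)
  st2 <- init_lattice(small_cfg())
  expect_identical(st$hotspots, st2$hotspots)
  expect_identical({set.seed(0); init_lattice(small_cfg()); runif(3)},
                   {set.seed(0); init_lattice(small_cfg()); runif(3)})

  expect_error(lattice_config(L = -1), "invalid")
  expect_error(lattice_config(vesicle_radius_range = c(0, 5)), "radius")
})

test_that("endocytosis removes exactly the receptors in the affected disc", {
  # empty region: nothing happens
  st <- init_lattice(small_cfg())
  endocytosis_event(st)
  expect_equal(st$surface_count, 0L)
  expect_equal(st$internal_pool, st$n_total)

  # fully occupied lattice, single radius r: drop equals the disc site count
  for (r in c(5L, 7L, 10L)) {
    cfg <- lattice_config(L = 0.625, grid_spacing = 5,
                          vesicle_radius_range = c(r, r),
                          n_total = 125L^2, seed = 2)
    st <- init_lattice(cfg)
    st$occupancy[] <- 1L
    st$surface_count <- st$n_total
    st$internal_pool <- 0L
    endocytosis_event(st)
    expect_equal(st$n_total - st$surface_count, disc_size(r))
    expect_equal(st$internal_pool, disc_size(r))
    # locality: removed sites form one wrapped disc; all others untouched
    expect_equal(sum(st$occupancy == 0L), disc_size(r))
  }
})

test_that("exocytosis respects pool, capacity and site availability", {
  cfg <- small_cfg()
  st <- init_lattice(cfg)

  # empty internal pool: no placement
  st$internal_pool <- 0L
  exocytosis_event(st)
  expect_equal(st$surface_count, 0L)

  # fully occupied target region: availability clause blocks placement
  st2 <- init_lattice(cfg)
  st2$occupancy[] <- 1L
  st2$surface_count <- st2$n_total
  st2$internal_pool <- 50L
  st2$n_total <- st2$n_total + 50L
  exocytosis_event(st2)
  expect_equal(st2$internal_pool, 50L)

  # receptor conservation holds through a long mixed event sequence
  st3 <- init_lattice(cfg)
  for (i in 1:300) {
    if (runif(1) < 0.5) endocytosis_event(st3) else exocytosis_event(st3)
    expect_equal(st3$surface_count + st3$internal_pool, st3$n_total)
    expect_equal(sum(st3$occupancy > 0L), st3$surface_count)
  }
})

test_that("exocytosis centers follow the wrapped hot-spot Gaussian", {
  n <- 125L
  cfg <- lattice_config(L = 0.625, grid_spacing = 5, seed = 8,
                        hotspots = list(centers = matrix(c(30L, 90L), 1),
                                        sigma = matrix(10, 1, 2),
                                        weights = 1))
  st <- init_lattice(cfg)
  ctr <- t(replicate(20000, kdelclust:::.exo_center(st)))
  # empirical CDF of the row coordinate vs the wrapped normal CDF
  wrapped_cdf <- function(x, mu, s, n) {
    ks <- -5:5
    sapply(x, function(v) sum(stats::pnorm(v + 0.5, mu + ks * n, s) -
                              stats::pnorm(0.5, mu + ks * n, s)))
  }
  emp <- cumsum(tabulate(ctr[, 1], n)) / nrow(ctr)
  theo <- wrapped_cdf(seq_len(n), 30, 10, n)
  expect_lt(max(abs(emp - theo)), 0.02)
  emp2 <- cumsum(tabulate(ctr[, 2], n)) / nrow(ctr)
  theo2 <- wrapped_cdf(seq_len(n), 90, 10, n)
  expect_lt(max(abs(emp2 - theo2)), 0.02)
})

test_that("pure endocytosis empties the surface and runs are reproducible", {
  cfg <- lattice_config(L = 0.625, grid_spacing = 5, kappa_endo = 5e-4,
                        kappa_exo = 0, duration = 3e4, seed = 4,
                        hotspots = "uniform")
  st <- init_lattice(cfg)
  # seed the surface directly with 500 receptors
  idx <- sample.int(125L^2, 500)
  st$occupancy[idx] <- 1L
  st$surface_count <- 500L
  st$internal_pool <- st$n_total - 500L
  tr <- simulate_lattice(cfg, state = st)
  expect_equal(tr$f[length(tr$f)], 0)

  tr1 <- simulate_lattice(small_cfg())
  tr2 <- simulate_lattice(small_cfg())
  expect_identical(tr1$f, tr2$f)

  expect_error(simulate_lattice(lattice_config(L = 0.625, grid_spacing = 5,
                                               kappa_endo = 10, duration = 1e8)),
               "too large")
})

test_that("steady state approaches the mean-field level and time", {
  cfg <- lattice_config(L = 1.25, grid_spacing = 5, kappa_endo = 1e-4,
                        kappa_exo = 0.5e-4, hotspots = "uniform",
                        vesicle_radius_range = c(2, 4),
                        duration = 6e4, seed = 31)
  est <- estimate_saturation(simulate_lattice(cfg))
  fs_mf <- steady_state_fraction(rate_pair(1e-4, 0.5e-4))
  ts_mf <- characteristic_time(rate_pair(1e-4, 0.5e-4))
  expect_lt(abs(est$f_s_hat - fs_mf) / fs_mf, 0.15)
  expect_lt(abs(est$t_s_hat - ts_mf) / ts_mf, 0.25)
})

test_that("steady level falls with endocytosis and rises with exocytosis", {
  run_fs <- function(ke, kx) {
    cfg <- lattice_config(L = 1.25, grid_spacing = 5, kappa_endo = ke,
                          kappa_exo = kx, hotspots = "uniform",
                          vesicle_radius_range = c(2, 4),
                          duration = 3e4, seed = 77)
    tr <- simulate_lattice(cfg)
    mean(tr$f[tr$times > 2e4])
  }
  base <- run_fs(1e-4, 0.5e-4)
  expect_lt(run_fs(3e-4, 0.5e-4), base)
  expect_gt(run_fs(1e-4, 1.5e-4), base)
})

test_that("saturation estimates recover closed-form and degenerate inputs", {
  t <- seq(0, 4000, by = 5)
  traj <- list(times = t, f = 0.4 * (1 - exp(-t / 500)))
  est <- estimate_saturation(traj)
  expect_equal(est$t_s_hat, 500, tolerance = 0.03)
  expect_equal(est$f_s_hat, 0.4, tolerance = 0.01)

  const <- list(times = seq(0, 90, 10), f = rep(0.25, 10))
  estc <- estimate_saturation(const)
  expect_equal(estc$t_s_hat, 0)
  expect_equal(estc$f_s_hat, 0.25)
  expect_equal(estc$fluctuation, 0)

  drift <- list(times = seq_len(40), f = seq(0, 1, length.out = 40))
  expect_error(estimate_saturation(drift), "no steady window")
})

test_that("lattice cluster distributions agree with a periodic flood-fill oracle", {
  cfg <- small_cfg()
  st <- init_lattice(cfg)
  expect_error(state_cluster_distribution(st), "empty surface")

  # single receptor
  st$occupancy[300] <- 1L
  st$surface_count <- 1L
  st$internal_pool <- st$n_total - 1L
  d1 <- state_cluster_distribution(st)
  expect_equal(d1$labeling$sizes, 1L)

  # checkerboard at 4-connectivity: all clusters are singletons
  n <- 40L
  chk <- outer(1:n, 1:n, function(i, j) (i + j) %% 2 == 0)
  lab <- label_clusters(chk, 4, periodic = TRUE)
  expect_true(all(lab$sizes == 1L))

  # random occupancy vs wrap-around flood fill
  set.seed(14)
  m <- random_mask(40, 40, 0.3)
  got <- label_clusters(m, 4, periodic = TRUE)
  want <- flood_fill_labels(m, 4, periodic = TRUE)
  expect_same_labeling(got$labels, want)
  expect_equal(sort(got$sizes), sort(as.integer(table(want[want > 0]))))
})

test_that("hot-spot delivery yields heavier cluster-size tails than uniform", {
  # few, tight hot spots so that repeated vesicle arrivals stack into
  # dense aggregates (the concentration regime of the full-size system)
  run_sizes <- function(hs) {
    cfg <- lattice_config(L = 1.25, grid_spacing = 5, hotspots = hs,
                          n_hotspots = 3, hotspot_sigma = 8,
                          duration = 2.5e4, seed = 19)
    tr <- simulate_lattice(cfg)
    state_cluster_distribution(tr$final_state)$labeling$sizes
  }
  hot <- run_sizes("default")
  uni <- run_sizes("uniform")
  med <- stats::median(c(hot, uni))
  tail_mass <- function(s) sum(s[s > med]) / sum(s)
  expect_gt(tail_mass(hot), tail_mass(uni))
})
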