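#' Configuration of the endo/exocytosis lattice simulator
#'
#' The plasma membrane is a periodic square lattice whose sites are
#' empty or hold one receptor. Endocytosis events excise all receptors
#' in a random disc; exocytosis events deliver receptors from the
#' internal pool into a disc centered at a point drawn from a
#' multi-peaked Gaussian hot-spot distribution (vesicle arrival sites
#' where microtubules meet the membrane). Event frequencies are
#' calibrated so that the realized mean per-surface-receptor loss rate
#' is `kappa_endo` and the mean per-internal-receptor delivery rate is
#' `kappa_exo`, making trajectories directly comparable with the
#' master-equation theory (see [master_equation]).
#'
#' @param L linear system size, micrometres (default 10, a small cell).
#' @param grid_spacing lattice constant, nanometres (default 5, the
#'   receptor scale). The lattice side is `round(1000 * L /
#'   grid_spacing)` sites.
#' @param kappa_endo per-receptor internalization rate, 1/s.
#' @param kappa_exo per-internal-receptor delivery rate, 1/s.
#' @param vesicle_radius_range inclusive integer radius range of the
#'   affected disc, lattice sites (default `c(5, 10)`: 50-100 nm
#'   vesicles at 5 nm spacing).
#' @param vesicle_capacity maximum receptors per arriving vesicle;
#'   `NULL` (default) means the drawn disc's site count (a vesicle can
#'   at most tile its footprint).
#' @param hotspots delivery-target distribution: `"default"` draws
#'   `n_hotspots` uniformly random peak centers (fixed per seed) with
#'   isotropic width `hotspot_sigma` and equal weights; `"uniform"`
#'   delivers uniformly over the lattice; or a list with `centers`
#'   (k x 2 matrix of site coordinates), `sigma` (k x 2 per-axis widths)
#'   and `weights` (summing to 1).
#' @param n_hotspots,hotspot_sigma defaults for `hotspots = "default"`:
#'   10 peaks of width 40 sites (200 nm).
#' @param n_total total receptor count (surface + internal); `NULL`
#'   (default) means 10% of the site count.
#' @param duration simulated time, seconds.
#' @param record_interval trajectory sampling interval, seconds.
#' @param ligand_fraction probability that a delivered receptor carries
#'   ligand; the flag is bookkeeping only and has no dynamical effect.
#' @param seed RNG seed.
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(L = 10, grid_spacing = 5,
                           kappa_endo = 1e-4, kappa_exo = 0.5e-4,
                           vesicle_radius_range = c(5L, 10L),
                           vesicle_capacity = NULL,
                           hotspots = "default",
                           n_hotspots = 10, hotspot_sigma = 40,
                           n_total = NULL,
                           duration = 1e4, record_interval = NULL,
                           ligand_fraction = 0.5, seed = 1L) {
  if (L <= 0 || grid_spacing <= 0) stop("invalid lattice dimensions")
  if (kappa_endo < 0 || kappa_exo < 0) stop("rates must be >= 0")
  n_side <- as.integer(round(1000 * L / grid_spacing))
  r <- as.integer(vesicle_radius_range)
  if (r[1] < 1 || r[2] < r[1] || r[2] > n_side %/% 2)
    stop("vesicle radius range must lie within [1, lattice side / 2]")
  if (is.null(n_total)) n_total <- as.integer(round(0.1 * n_side^2))
  if (is.null(record_interval)) record_interval <- duration / 200
  structure(list(
    L = L, grid_spacing = grid_spacing, n_side = n_side,
    kappa_endo = kappa_endo, kappa_exo = kappa_exo,
    vesicle_radius_range = r, vesicle_capacity = vesicle_capacity,
    hotspots = hotspots, n_hotspots = n_hotspots,
    hotspot_sigma = hotspot_sigma, n_total = as.integer(n_total),
    duration = duration, record_interval = record_interval,
    ligand_fraction = ligand_fraction, seed = as.integer(seed)),
    class = "lattice_config")
}

# integer offsets (dr, dc) of the Euclidean disc of radius r
.disc_offsets <- function(rmin, rmax) {
  lapply(seq.int(rmin, rmax), function(r) {
    g <- expand.grid(dr = -r:r, dc = -r:r)
    g <- g[g$dr^2 + g$dc^2 <= r^2, ]
    list(dr = as.integer(g$dr), dc = as.integer(g$dc), n = nrow(g))
  })
}

#' Initialize a lattice state
#'
#' Seeds the RNG from the config, resolves the hot-spot layout (peak
#' centers are drawn once here so they are fixed per seed) and returns
#' the initial state: an empty surface with all `n_total` receptors in
#' the internal pool, f(0) = 0.
#'
#' The state is an environment and is modified in place by the event
#' functions; copy with [copy_lattice_state()] if a snapshot is needed.
#'
#' @param config a [lattice_config()].
#' @return An object of class `lattice_state` with fields `occupancy`
#'   (integer vector of length n_side^2; 0 empty, 1 unliganded,
#'   2 liganded), `internal_pool`, `surface_count`, `time`, `n_side`,
#'   `n_total`, `hotspots`, `discs`, `config`.
#' @export
init_lattice <- function(config) {
  stopifnot(inherits(config, "lattice_config"))
  set.seed(config$seed)
  n <- config$n_side
  hs <- config$hotspots
  if (identical(hs, "default")) {
    k <- config$n_hotspots
    hs <- list(centers = cbind(sample.int(n, k, replace = TRUE),
                               sample.int(n, k, replace = TRUE)),
               sigma = matrix(config$hotspot_sigma, k, 2),
               weights = rep(1 / k, k))
  }
  if (is.list(hs) && abs(sum(hs$weights) - 1) > 1e-9)
    stop("hotspot weights must sum to 1")
  st <- new.env(parent = emptyenv())
  st$occupancy <- integer(n * n)
  st$internal_pool <- config$n_total
  st$surface_count <- 0L
  st$time <- 0
  st$n_side <- n
  st$n_total <- config$n_total
  st$hotspots <- hs
  st$discs <- .disc_offsets(config$vesicle_radius_range[1],
                            config$vesicle_radius_range[2])
  st$config <- config
  class(st) <- "lattice_state"
  st
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf(paste0("lattice_state: %d x %d sites, t = %.4g s, ",
                     "%d on surface (f = %.4f), %d internal\n"),
              x$n_side, x$n_side, x$time, x$surface_count,
              surface_fraction(x), x$internal_pool))
  invisible(x)
}

#' Deep-copy a lattice state (states are mutable environments)
#' @param state a `lattice_state`.
#' @return An independent copy.
#' @export
copy_lattice_state <- function(state) {
  st <- new.env(parent = emptyenv())
  for (nm in ls(state)) assign(nm, get(nm, envir = state), envir = st)
  class(st) <- "lattice_state"
  st
}

#' Surface fraction f of a lattice state
#' @param state a `lattice_state`.
#' @return `surface_count / n_total`, in `[0, 1]`.
#' @export
surface_fraction <- function(state) state$surface_count / state$n_total

# linear indices of the disc `disc` centered at (ci, cj), periodic wrap
.disc_index <- function(state, ci, cj, disc) {
  n <- state$n_side
  rows <- (ci - 1L + disc$dr) %% n
  cols <- (cj - 1L + disc$dc) %% n
  cols * n + rows + 1L
}

#' Apply one endocytosis event
#'
#' A uniformly random site is the event center; the disc radius is
#' uniform on the configured range; every receptor in the disc is moved
#' from the surface to the internal pool. Receptor number is conserved.
#'
#' @param state a `lattice_state` (modified in place).
#' @return The state, invisibly.
#' @export
endocytosis_event <- function(state) {
  n <- state$n_side
  ci <- sample.int(n, 1L)
  cj <- sample.int(n, 1L)
  disc <- state$discs[[sample.int(length(state$discs), 1L)]]
  idx <- .disc_index(state, ci, cj, disc)
  hit <- idx[state$occupancy[idx] > 0L]
  if (length(hit)) {
    state$occupancy[hit] <- 0L
    state$surface_count <- state$surface_count - length(hit)
    state$internal_pool <- state$internal_pool + length(hit)
  }
  invisible(state)
}

# draw an exocytosis target center from the hot-spot mixture
.exo_center <- function(state) {
  n <- state$n_side
  hs <- state$hotspots
  if (identical(hs, "uniform"))
    return(c(sample.int(n, 1L), sample.int(n, 1L)))
  p <- if (length(hs$weights) > 1L)
    sample.int(length(hs$weights), 1L, prob = hs$weights) else 1L
  c((as.integer(round(rnorm(1, hs$centers[p, 1], hs$sigma[p, 1]))) - 1L) %% n + 1L,
    (as.integer(round(rnorm(1, hs$centers[p, 2], hs$sigma[p, 2]))) - 1L) %% n + 1L)
}

#' Apply one exocytosis (vesicle arrival) event
#'
#' The target center is drawn from the hot-spot mixture (wrapped
#' periodically); the vesicle radius is uniform on the configured range;
#' the number of receptors carried is uniform on {0, ..., capacity} and
#' is additionally limited by the internal pool and by the empty sites
#' available in the target disc (surplus receptors stay internal).
#'
#' @param state a `lattice_state` (modified in place).
#' @return The state, invisibly.
#' @export
exocytosis_event <- function(state) {
  ctr <- .exo_center(state)
  disc <- state$discs[[sample.int(length(state$discs), 1L)]]
  idx <- .disc_index(state, ctr[1], ctr[2], disc)
  cap <- state$config$vesicle_capacity
  if (is.null(cap)) cap <- disc$n else cap <- min(cap, disc$n)
  carried <- sample.int(cap + 1L, 1L) - 1L
  if (carried == 0L || state$internal_pool == 0L) return(invisible(state))
  empty <- idx[state$occupancy[idx] == 0L]
  k <- min(carried, state$internal_pool, length(empty))
  if (k > 0L) {
    dest <- if (length(empty) == 1L) empty else
      empty[sample.int(length(empty), k)]
    lig <- runif(k) < state$config$ligand_fraction
    state$occupancy[dest] <- ifelse(lig, 2L, 1L)
    state$surface_count <- state$surface_count + k
    state$internal_pool <- state$internal_pool - k
  }
  invisible(state)
}

#' Run the endo/exocytosis lattice simulation
#'
#' Continuous-time kinetic (Gillespie) scheduling: endocytosis events
#' occur at total rate `kappa_endo * n_sites / mean_disc_area` — so a
#' surface receptor, hit with probability disc_area/n_sites per event,
#' is internalized at mean rate `kappa_endo` — and exocytosis events at
#' total rate `kappa_exo * internal_pool / (mean_capacity/2)`, so the
#' mean per-internal-receptor delivery rate is `kappa_exo` (up to the
#' occupancy cap in crowded target regions). The surface fraction f is
#' recorded on a regular grid of sampling times.
#'
#' @param config a [lattice_config()].
#' @param state optionally, a pre-built [init_lattice()] state to
#'   continue from (the config's seed is not re-applied then).
#' @return An object of class `lattice_trajectory`: `times`, `f`
#'   (surface fraction), `surface_count`, `config`, and `final_state`.
#' @export
simulate_lattice <- function(config, state = NULL) {
  stopifnot(inherits(config, "lattice_config"))
  if (config$duration <= 0) stop("duration must be > 0")
  if (is.null(state)) state <- init_lattice(config)
  n_sites <- as.numeric(state$n_side)^2
  abar <- mean(vapply(state$discs, `[[`, numeric(1), "n"))
  cap <- config$vesicle_capacity
  dbar <- if (is.null(cap)) abar / 2 else
    mean(vapply(state$discs, function(d) min(cap, d$n), numeric(1))) / 2
  rate_endo <- config$kappa_endo * n_sites / abar
  rate_exo_max <- config$kappa_exo * config$n_total / dbar
  expected_events <- config$duration * (rate_endo + rate_exo_max)
  if (expected_events > 5e7)
    stop("expected event count ", format(expected_events, digits = 3),
         " is too large; reduce duration, rates or lattice size, or ",
         "increase grid_spacing")

  rec_t <- seq(0, config$duration, by = config$record_interval)
  rec_f <- numeric(length(rec_t))
  rec_s <- integer(length(rec_t))
  ri <- 1L
  t <- state$time
  repeat {
    rate_exo <- config$kappa_exo * state$internal_pool / dbar
    total <- rate_endo + rate_exo
    t_next <- if (total > 0) t + rexp(1, total) else Inf
    while (ri <= length(rec_t) && rec_t[ri] < t_next) {
      rec_f[ri] <- surface_fraction(state)
      rec_s[ri] <- state$surface_count
      ri <- ri + 1L
    }
    if (t_next > config$duration) break
    t <- t_next
    state$time <- t
    if (runif(1) * total < rate_endo) endocytosis_event(state)
    else exocytosis_event(state)
  }
  state$time <- config$duration
  structure(list(times = rec_t, f = rec_f, surface_count = rec_s,
                 config = config, final_state = state),
            class = "lattice_trajectory")
}

#' @export
print.lattice_trajectory <- function(x, ...) {
  cat(sprintf(paste0("lattice_trajectory: %d samples over %.4g s, ",
                     "final f = %.4f\n"),
              length(x$times), max(x$times), x$f[length(x$f)]))
  invisible(x)
}

#' Estimate the saturation level and time of a trajectory
#'
#' The saturation level f_s is the mean surface fraction over the
#' trailing quarter of the trajectory; the window must be statistically
#' steady (its two halves agreeing within 2 pooled standard errors).
#' The saturation time t_s is the first time f reaches a (1 - 1/e)
#' fraction of f_s.
#'
#' @param traj a `lattice_trajectory`, or any list with `times` and `f`.
#' @param steady_window trailing fraction used for the steady state
#'   (default 0.25).
#' @return An object of class `saturation_estimate`: `f_s_hat`,
#'   `t_s_hat` (s), `fluctuation` (SD of f in the steady window).
#' @export
estimate_saturation <- function(traj, steady_window = 0.25) {
  t <- traj$times; f <- traj$f
  n <- length(f)
  if (n < 8L) stop("trajectory too short")
  iw <- seq.int(n - max(4L, ceiling(steady_window * n)) + 1L, n)
  w <- f[iw]
  if (!.is_stationary(w))
    stop("no steady window found: trajectory still drifting")
  fs <- mean(w)
  i <- which(f >= (1 - exp(-1)) * fs)[1]
  if (is.na(i)) stop("no steady window found: f never reaches (1 - 1/e) f_s")
  structure(list(f_s_hat = fs, t_s_hat = t[i], fluctuation = stats::sd(w)),
            class = "saturation_estimate")
}

#' @export
print.saturation_estimate <- function(x, ...) {
  cat(sprintf("saturation_estimate: f_s = %.4f +/- %.4f, t_s = %.4g s\n",
              x$f_s_hat, x$fluctuation, x$t_s_hat))
  invisible(x)
}

#' Cluster-size distribution of a lattice state
#'
#' Labels the occupied sites with periodic Hoshen-Kopelman labeling
#' (4-connectivity by default, the lattice convention) and log-bins the
#' cluster sizes — the simulation counterpart of the imaging pipeline's
#' distribution.
#'
#' @param state a `lattice_state`.
#' @param connectivity 4 (default) or 8.
#' @param bins_per_decade log-binning resolution (default 5).
#' @return A list with the `cluster_labeling` and the
#'   `size_distribution`.
#' @export
state_cluster_distribution <- function(state, connectivity = 4,
                                       bins_per_decade = 5) {
  if (state$surface_count == 0L)
    stop("empty surface: no clusters to measure")
  occ <- matrix(state$occupancy > 0L, state$n_side, state$n_side)
  lab <- label_clusters(occ, connectivity = connectivity, periodic = TRUE)
  list(labeling = lab,
       distribution = size_distribution(lab$sizes, bins_per_decade))
}
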