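#' Two-state master-equation theory of the surface receptor fraction
#'
#' The fraction f of a cell's receptors residing on its surface obeys
#' df/dt = -kappa_endo * f + kappa_exo * (1 - f): receptors leave the
#' surface by endocytosis at per-receptor rate kappa_endo and return from
#' the internal pool by exocytosis at per-internal-receptor rate
#' kappa_exo. The solution relaxes exponentially to the steady fraction
#' f_s = kappa_exo / (kappa_endo + kappa_exo) with characteristic time
#' t_s = 1 / (kappa_endo + kappa_exo).
#'
#' @param kappa_endo endocytosis rate, 1/s, >= 0.
#' @param kappa_exo exocytosis rate, 1/s, >= 0.
#' @return `rate_pair` returns a validated object of class `rate_pair`.
#' @name master_equation
NULL

#' @rdname master_equation
#' @export
rate_pair <- function(kappa_endo, kappa_exo) {
  if (kappa_endo < 0 || kappa_exo < 0) stop("rates must be >= 0")
  structure(list(kappa_endo = kappa_endo, kappa_exo = kappa_exo),
            class = "rate_pair")
}

#' Reference endo/exocytosis rates of cluster-forming cells
#'
#' A representative point in the bulk of the experimentally accessible
#' rate region: kappa_endo = 1e-4/s, kappa_exo = 0.5e-4/s.
#' @export
reference_rates <- function() rate_pair(1e-4, 0.5e-4)

.as_rates <- function(rates, kappa_exo) {
  if (inherits(rates, "rate_pair")) rates
  else rate_pair(rates, kappa_exo)
}

#' @rdname master_equation
#' @param rates a `rate_pair`, or `kappa_endo` when `kappa_exo` is given.
#' @return `steady_state_fraction` returns f_s in `[0, 1]`.
#' @export
steady_state_fraction <- function(rates, kappa_exo = NULL) {
  r <- .as_rates(rates, kappa_exo)
  tot <- r$kappa_endo + r$kappa_exo
  if (tot <= 0) stop("kappa_endo + kappa_exo must be > 0")
  r$kappa_exo / tot
}

#' @rdname master_equation
#' @return `characteristic_time` returns t_s in seconds.
#' @export
characteristic_time <- function(rates, kappa_exo = NULL) {
  r <- .as_rates(rates, kappa_exo)
  tot <- r$kappa_endo + r$kappa_exo
  if (tot <= 0) stop("kappa_endo + kappa_exo must be > 0")
  1 / tot
}

#' @rdname master_equation
#' @param f0 initial surface fraction in `[0, 1]`.
#' @param t time(s) since treatment start, seconds, >= 0.
#' @return `master_equation_solution` returns f(t) =
#'   f_s + (f0 - f_s) exp(-t / t_s), vectorized over `t`.
#' @export
master_equation_solution <- function(rates, f0, t, kappa_exo = NULL) {
  r <- .as_rates(rates, kappa_exo)
  if (f0 < 0 || f0 > 1) stop("f0 must lie in [0, 1]")
  if (any(t < 0)) stop("t must be >= 0")
  fs <- steady_state_fraction(r)
  ts <- characteristic_time(r)
  fs + (f0 - fs) * exp(-t / ts)
}

#' Experimentally constrained region of the rate phase space
#'
#' Bundles the observational bounds that delimit the (kappa_endo,
#' kappa_exo) region compatible with cluster-forming cells: the observed
#' growth-regime durations bound t_s in [ts_min, ts_max], the steady
#' saturation level is bounded in [fs_min, fs_max], and levels below the
#' threshold fs_c are experimentally undetectable. Only the ratio
#' fs_max/fs_min is measurable from image series; fs_min is derived from
#' an assumed fs_max via [fs_min_from_ratio()].
#'
#' @param ts_min,ts_max bounds on the characteristic time, seconds.
#' @param fs_max assumed maximal steady surface fraction (default 0.5:
#'   at most half of all receptors on the membrane).
#' @param fs_ratio observed fs_max / fs_min ratio (default 1.85).
#' @param fs_c detectability threshold on f_s (default 0.02).
#' @return An object of class `phase_space_spec`.
#' @export
phase_space_spec <- function(ts_min, ts_max, fs_max = 0.5, fs_ratio = 1.85,
                             fs_c = 0.02) {
  if (ts_min > ts_max || ts_min <= 0) stop("need 0 < ts_min <= ts_max")
  fs_min <- fs_min_from_ratio(fs_max, fs_ratio)
  if (!(fs_c > 0 && fs_c < fs_min))
    stop("fs_c must lie in (0, fs_min)")
  structure(list(ts_min = ts_min, ts_max = ts_max, fs_min = fs_min,
                 fs_max = fs_max, fs_ratio = fs_ratio, fs_c = fs_c),
            class = "phase_space_spec")
}

#' Derive the lower saturation bound from the observed fluctuation ratio
#'
#' @param fs_max assumed maximal steady fraction in (0, 1].
#' @param ratio fs_max / fs_min, >= 1.
#' @return fs_min = fs_max / ratio.
#' @export
fs_min_from_ratio <- function(fs_max, ratio) {
  if (!(fs_max > 0 && fs_max <= 1)) stop("fs_max must lie in (0, 1]")
  if (ratio < 1) stop("ratio must be >= 1")
  fs_max / ratio
}

#' Characteristic-time border lines in the rate phase space
#'
#' The loci kappa_endo + kappa_exo = 1/ts are straight lines of slope -1;
#' the two lines at ts_min and ts_max bound the band of rate pairs whose
#' relaxation time matches the observed growth-regime durations.
#'
#' @param spec a [phase_space_spec()].
#' @return An object of class `ts_borders` with the two rate sums and a
#'   membership predicate usable via [phase_space_contains()].
#' @export
ts_border_lines <- function(spec) {
  structure(list(
    sum_fast = 1 / spec$ts_min,   # upper border: larger total rate
    sum_slow = 1 / spec$ts_max,
    contains = function(r) {
      s <- r$kappa_endo + r$kappa_exo
      s >= 1 / spec$ts_max & s <= 1 / spec$ts_min
    }),
    class = "ts_borders")
}

#' Saturation-level border lines in the rate phase space
#'
#' A fixed steady fraction f_s traces the ray kappa_endo =
#' (-1 + 1/f_s) * kappa_exo; the rays at fs_min and fs_max bound the
#' wedge of rate pairs whose saturation level is experimentally
#' observed.
#'
#' @param spec a [phase_space_spec()].
#' @return An object of class `fs_borders` with the two slopes
#'   (kappa_endo per kappa_exo) and a membership predicate.
#' @export
fs_border_lines <- function(spec) {
  if (!(spec$fs_min > 0 && spec$fs_max < 1))
    stop("fs bounds must lie strictly inside (0, 1)")
  structure(list(
    slope_at_fs_min = -1 + 1 / spec$fs_min,  # steeper ray (smaller f_s)
    slope_at_fs_max = -1 + 1 / spec$fs_max,
    contains = function(r) {
      fs <- steady_state_fraction(r)
      fs >= spec$fs_min & fs <= spec$fs_max
    }),
    class = "fs_borders")
}

#' Test whether a rate pair lies inside the constrained region
#'
#' @param border a `ts_borders` or `fs_borders` object (or a list of
#'   them, all of which must admit the point).
#' @param rates a [rate_pair()].
#' @return Logical.
#' @export
phase_space_contains <- function(border, rates) {
  if (inherits(border, c("ts_borders", "fs_borders")))
    return(border$contains(rates))
  all(vapply(border, function(b) b$contains(rates), logical(1)))
}

#' Endocytosis rate needed to push clustering below detectability
#'
#' Inverts the steady-state relation on the threshold line f_s = fs_c:
#' kappa_endo = (-1 + 1/fs_c) * kappa_exo. At the reference exocytosis
#' rate 0.5e-4/s and fs_c = 0.02 this gives 24.5e-4/s, about 25-fold the
#' reference endocytosis rate.
#'
#' @param kappa_exo exocytosis rate, 1/s, > 0.
#' @param fs_c detectability threshold in (0, 1).
#' @return kappa_endo in 1/s.
#' @export
required_endo_rate <- function(kappa_exo, fs_c) {
  if (!(fs_c > 0 && fs_c < 1)) stop("fs_c must lie in (0, 1)")
  if (kappa_exo <= 0) stop("kappa_exo must be > 0")
  (-1 + 1 / fs_c) * kappa_exo
}

#' Exocytosis rate needed to push clustering below detectability
#'
#' kappa_exo = kappa_endo * fs_c / (1 - fs_c). At the reference
#' endocytosis rate 1e-4/s and fs_c = 0.02 this gives about 0.02e-4/s,
#' about 25-fold below the reference exocytosis rate.
#'
#' @param kappa_endo endocytosis rate, 1/s, > 0.
#' @param fs_c detectability threshold in (0, 1).
#' @return kappa_exo in 1/s.
#' @export
required_exo_rate <- function(kappa_endo, fs_c) {
  if (!(fs_c > 0 && fs_c < 1)) stop("fs_c must lie in (0, 1)")
  if (kappa_endo <= 0) stop("kappa_endo must be > 0")
  kappa_endo * fs_c / (1 - fs_c)
}

#' Effective endocytosis rate at partial surface occupation
#'
#' Endocytosis requires receptors to be present in the excised patch, so
#' at surface occupation density n the observable internalization rate
#' is kappa_endo' = n * kappa_endo.
#'
#' @param n surface occupation density in `[0, 1]`.
#' @param kappa_endo bare endocytosis rate, 1/s.
#' @return The effective rate n * kappa_endo.
#' @export
effective_endo_rate <- function(n, kappa_endo) {
  if (n < 0 || n > 1) stop("n must lie in [0, 1]")
  n * kappa_endo
}

#' Rasterize t_s and f_s over a log-spaced rate grid
#'
#' Convenience export for phase-space heat maps: evaluates the
#' characteristic time and saturation level on a log-spaced grid of
#' (kappa_endo, kappa_exo) pairs.
#'
#' @param endo_range,exo_range length-2 rate ranges, 1/s.
#' @param n grid points per axis.
#' @return A data.frame with kappa_endo, kappa_exo, t_s, f_s.
#' @export
phase_space_raster <- function(endo_range, exo_range, n = 50) {
  ke <- 10^seq(log10(endo_range[1]), log10(endo_range[2]), length.out = n)
  kx <- 10^seq(log10(exo_range[1]), log10(exo_range[2]), length.out = n)
  g <- expand.grid(kappa_endo = ke, kappa_exo = kx)
  g$t_s <- 1 / (g$kappa_endo + g$kappa_exo)
  g$f_s <- g$kappa_exo / (g$kappa_endo + g$kappa_exo)
  g
}
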