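#' Geometric summary of a segmented cell region
#'
#' Computes the cell area, a Crofton-style perimeter and the equal-area
#' circle diameter used to summarize cell size. The Crofton estimate
#' multiplies the count of exposed pixel edges by pi/4, which is unbiased
#' for smooth convex outlines (the relevant case for cell masks) where
#' the raw edge count overestimates the contour length.
#'
#' @param cell_mask logical matrix, TRUE inside the cell.
#' @param pixel_size micrometres per pixel.
#' @return An object of class `cell_geometry`: `cell_mask`, `area` (um^2),
#'   `perimeter` (um), `equivalent_diameter` (um).
#' @export
cell_geometry <- function(cell_mask, pixel_size) {
  if (!is.matrix(cell_mask)) stop("'cell_mask' must be a matrix")
  if (!is.logical(cell_mask)) cell_mask <- cell_mask != 0
  npix <- sum(cell_mask)
  if (npix == 0L) stop("empty cell mask")
  area <- npix * pixel_size^2
  structure(list(
    cell_mask = cell_mask,
    area = area,
    perimeter = (pi / 4) * .boundary_edges(cell_mask) * pixel_size,
    equivalent_diameter = 2 * sqrt(area / pi)),
    class = "cell_geometry")
}

# number of unit edges between an occupied pixel and an empty/outside one
.boundary_edges <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  sum(core & !pad[1:nr, 2:(nc + 1L)]) +
    sum(core & !pad[3:(nr + 2L), 2:(nc + 1L)]) +
    sum(core & !pad[2:(nr + 1L), 1:nc]) +
    sum(core & !pad[2:(nr + 1L), 3:(nc + 2L)])
}

#' Surface-density time series of cluster signal
#'
#' For each frame, the above-threshold cluster area (occupied pixel
#' count) inside the cell is divided by the cell perimeter, giving a
#' signal measure per micrometre of cell periphery — the quantity whose
#' time course separates into transient, exponential-growth and
#' steady-state regimes.
#'
#' @param stack a [frame_stack()].
#' @param geometry a [cell_geometry()] whose mask matches the frame
#'   dimensions.
#' @param threshold_ratio peak-to-background ratio (> 1), see
#'   [segment_clusters()].
#' @param widths background smoothing widths, see [estimate_background()].
#' @return An object of class `density_timeseries`: `timestamps` (s) and
#'   `density` (occupied px per um of perimeter).
#' @export
density_timeseries <- function(stack, geometry, threshold_ratio = 1.5,
                               widths = c(4, 2)) {
  stopifnot(inherits(stack, "frame_stack"), inherits(geometry, "cell_geometry"))
  if (!identical(dim(geometry$cell_mask), dim(stack$frames[[1]])))
    stop("cell mask does not match frame dimensions")
  dens <- vapply(stack$frames, function(fr) {
    bg <- estimate_background(fr, widths)
    m <- segment_clusters(fr, bg, threshold_ratio)
    sum(m$grid & geometry$cell_mask) / geometry$perimeter
  }, numeric(1))
  structure(list(timestamps = stack$timestamps, density = dens),
            class = "density_timeseries")
}

#' Segment a density time course into transient, growth and steady regimes
#'
#' The steady-state level is the mean over the trailing quarter of the
#' series (with a stationarity check: the two halves of that window must
#' agree within 2 pooled standard errors). The growth regime ends when
#' the density first reaches (1 - 1/e) of the steady mean — mirroring the
#' characteristic-time definition of the endo/exocytosis rate theory —
#' and the transient regime ends when the density first exceeds a small
#' fraction (default 5%) of the steady mean.
#'
#' @param series a `density_timeseries` (or any list with `timestamps`
#'   and `density`), at least 10 points.
#' @param transient_frac fraction of the steady mean that ends the
#'   transient regime (default 0.05).
#' @param steady_window trailing fraction of frames used for the steady
#'   state (default 0.25).
#' @return An object of class `regime_segmentation`: `transient_end`,
#'   `growth_end` (s), `steady_mean`, `steady_band` (mean +/- 1 SD).
#' @export
segment_regimes <- function(series, transient_frac = 0.05,
                            steady_window = 0.25) {
  t <- series$timestamps; y <- series$density
  n <- length(y)
  if (n < 10L) stop("need at least 10 time points")
  iw <- seq.int(n - max(4L, ceiling(steady_window * n)) + 1L, n)
  w <- y[iw]
  if (!.is_stationary(w))
    stop("no steady state detected: trailing window is not stationary")
  steady_mean <- mean(w)
  if (steady_mean <= 0)
    stop("no steady state detected: steady level is zero")
  ig <- which(y >= (1 - exp(-1)) * steady_mean)[1]
  it <- which(y > transient_frac * steady_mean)[1]
  if (is.na(ig))
    stop("no steady state detected: density never reaches (1 - 1/e) of the steady mean")
  transient_end <- t[min(it, ig)]
  growth_end <- t[ig]
  structure(list(
    transient_end = transient_end,
    growth_end = growth_end,
    steady_mean = steady_mean,
    steady_band = steady_mean + c(-1, 1) * stats::sd(w)),
    class = "regime_segmentation")
}

#' @export
print.regime_segmentation <- function(x, ...) {
  cat(sprintf(paste0("regime_segmentation: transient ends %.4g s, growth ",
                     "ends %.4g s,\n  steady mean %.4g (band %.4g .. %.4g)\n"),
              x$transient_end, x$growth_end, x$steady_mean,
              x$steady_band[1], x$steady_band[2]))
  invisible(x)
}
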