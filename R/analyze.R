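#' Run the full cluster-quantification pipeline on a frame stack
#'
#' Convenience driver: estimates the cell outline (unless supplied),
#' segments and labels clusters in every frame, accumulates the
#' log-binned cluster-size distribution with its power-law fit, and
#' computes the perimeter-scaled density time series with its regime
#' segmentation.
#'
#' @param stack a [frame_stack()].
#' @param cell_mask logical matrix outlining the cell; `NULL` (default)
#'   derives it by Otsu thresholding of the time-mean projection, the
#'   fallback used when no hand-drawn outline is available.
#' @param threshold_ratio,widths segmentation parameters, see
#'   [segment_clusters()] and [estimate_background()].
#' @param connectivity labeling connectivity (default 8, image blobs).
#' @param bins_per_decade,fit_range distribution parameters, see
#'   [size_distribution()] and [fit_power_law()].
#' @param min_frame first frame (index) whose clusters enter the size
#'   distribution (default 1; later frames only, e.g. steady state, can
#'   be selected).
#' @return A list of class `cluster_analysis`: `clusters` (data.frame:
#'   frame, label, size_px, area_um2, centroids), `distribution`,
#'   `fit` (`NULL` when too few bins), `series`, `regimes` (`NULL` when
#'   no steady state is reached), `geometry`.
#' @export
analyze_stack <- function(stack, cell_mask = NULL, threshold_ratio = 1.5,
                          widths = c(4, 2), connectivity = 8,
                          bins_per_decade = 5, fit_range = NULL,
                          min_frame = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(cell_mask)) {
    proj <- Reduce(`+`, stack$frames) / length(stack$frames)
    cell_mask <- proj > .otsu_threshold(proj)
  }
  geom <- cell_geometry(cell_mask, stack$pixel_size)
  tables <- vector("list", length(stack$frames))
  all_sizes <- integer(0)
  for (k in seq_along(stack$frames)) {
    fr <- stack$frames[[k]]
    msk <- segment_clusters(fr, estimate_background(fr, widths),
                            threshold_ratio)
    msk$grid <- msk$grid & geom$cell_mask
    lab <- label_clusters(msk, connectivity = connectivity)
    tb <- cluster_table(lab, stack$pixel_size)
    if (nrow(tb)) tb <- cbind(frame = k, tb)
    tables[[k]] <- tb
    if (k >= min_frame) all_sizes <- c(all_sizes, lab$sizes)
  }
  dist <- if (length(all_sizes)) size_distribution(all_sizes, bins_per_decade)
          else NULL
  fit <- if (!is.null(dist))
    tryCatch(fit_power_law(dist, fit_range), error = function(e) NULL)
  else NULL
  series <- density_timeseries(stack, geom, threshold_ratio, widths)
  regimes <- tryCatch(segment_regimes(series), error = function(e) NULL)
  structure(list(clusters = do.call(rbind, tables[lengths(tables) > 0]),
                 distribution = dist, fit = fit, series = series,
                 regimes = regimes, geometry = geom),
            class = "cluster_analysis")
}

# Otsu's between-class-variance-maximizing threshold on a numeric field
.otsu_threshold <- function(x, n_levels = 256L) {
  v <- as.numeric(x)
  br <- seq(min(v), max(v), length.out = n_levels + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_levels]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  mids[which.max(bcv)]
}

#' @export
print.cluster_analysis <- function(x, ...) {
  cat(sprintf("cluster_analysis: %d frames, %d cluster detections\n",
              length(x$series$timestamps),
              if (is.null(x$clusters)) 0L else nrow(x$clusters)))
  if (!is.null(x$fit))
    cat(sprintf("  size-distribution exponent alpha = %.3f (se %.3f)\n",
                x$fit$alpha, x$fit$stderr))
  if (!is.null(x$regimes))
    cat(sprintf("  regimes: transient to %.4g s, growth to %.4g s, steady %.4g\n",
                x$regimes$transient_end, x$regimes$growth_end,
                x$regimes$steady_mean))
  invisible(x)
}
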