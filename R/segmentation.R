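#' Anisotropic Gaussian smoothing of an intensity field
#'
#' Separable Gaussian convolution with per-axis standard deviations and
#' reflective boundary padding. Reflection conserves flat fields exactly
#' and keeps the total intensity approximately conserved at the image
#' border.
#'
#' @param field numeric matrix of finite intensities.
#' @param sigma length-2 numeric, standard deviations in pixels along the
#'   row (vertical) and column (horizontal) axes; both > 0.
#' @param truncate kernel half-width in units of sigma (default 4).
#' @return A matrix of the same dimensions.
#' @export
gaussian_smooth <- function(field, sigma, truncate = 4) {
  if (!all(is.finite(field))) stop("non-finite intensities in 'field'")
  sigma <- rep_len(as.numeric(sigma), 2L)
  if (any(sigma <= 0)) stop("smoothing widths must be > 0")
  out <- .smooth_axis(field, sigma[1], truncate)          # along rows
  t(.smooth_axis(t(out), sigma[2], truncate))             # along columns
}

# 1D Gaussian filter down each column, reflect-padded
.smooth_axis <- function(m, s, truncate) {
  r <- max(1L, as.integer(ceiling(truncate * s)))
  k <- stats::dnorm(seq(-r, r), sd = s)
  k <- k / sum(k)
  n <- nrow(m)
  # reflect indices: for n rows, pad with rows r..1 above and n..(n-r+1) below
  ridx <- pmin(pmax(.reflect_index(seq(1L - r, n + r), n), 1L), n)
  padded <- m[ridx, , drop = FALSE]
  filt <- stats::filter(padded, k, sides = 2)
  matrix(filt[(r + 1L):(r + n), ], nrow = n)
}

# mirror an out-of-range index into 1..n (boundary pixel not repeated
# beyond the single reflection needed for kernels up to ~n wide)
.reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

#' Estimate the smooth background of a fluorescence frame
#'
#' The local background around each intensity peak is estimated by
#' anisotropic Gaussian smoothing of the frame; bright, compact clusters
#' are spread into the local mean while the large-scale background is
#' preserved.
#'
#' @param frame numeric intensity matrix.
#' @param widths per-axis Gaussian standard deviations in pixels,
#'   `c(sigma_row, sigma_col)`. Default `c(4, 2)`.
#' @return An object of class `background_field` with elements `values`
#'   (matrix, same shape as `frame`) and `smoothing_params`.
#' @export
estimate_background <- function(frame, widths = c(4, 2)) {
  values <- gaussian_smooth(frame, widths)
  values[values < 0] <- 0
  structure(list(values = values, smoothing_params = rep_len(widths, 2L)),
            class = "background_field")
}

#' Segment receptor clusters by peak-to-background ratio thresholding
#'
#' A pixel is classified as cluster signal when its intensity exceeds
#' `threshold_ratio` times the local background. Where the background is
#' exactly zero, a pixel is occupied iff its own intensity is positive,
#' preserving the ratio semantics without dividing by zero.
#'
#' @param frame numeric intensity matrix.
#' @param background a `background_field` from [estimate_background()], or
#'   a plain matrix of background values.
#' @param threshold_ratio dimensionless ratio > 1 (default 1.5).
#' @return An object of class `binary_mask`: list with `grid` (logical
#'   matrix) and `threshold_ratio`.
#' @export
segment_clusters <- function(frame, background, threshold_ratio = 1.5) {
  bg <- if (inherits(background, "background_field")) background$values
        else background
  if (!identical(dim(frame), dim(bg)))
    stop("frame and background shapes differ")
  if (!is.numeric(threshold_ratio) || threshold_ratio <= 1)
    stop("'threshold_ratio' must be > 1")
  grid <- ifelse(bg == 0, frame > 0, frame > threshold_ratio * bg)
  structure(list(grid = grid, threshold_ratio = threshold_ratio),
            class = "binary_mask")
}
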