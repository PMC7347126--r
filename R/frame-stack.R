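#' Frame stacks: ordered grayscale intensity fields with timestamps
#'
#' A `frame_stack` holds the input of the imaging pipeline: an ordered list
#' of 2D non-negative intensity matrices, the acquisition timestamps
#' (seconds from treatment start) and the pixel size in micrometres.
#'
#' @param frames list of numeric matrices, all with identical dimensions,
#'   finite and non-negative.
#' @param timestamps numeric vector of acquisition times in seconds,
#'   strictly increasing, one per frame.
#' @param pixel_size pixel edge length in micrometres (> 0).
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, timestamps, pixel_size) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("'frames' must be a non-empty list of matrices")
  dims <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), dims))
      stop("all frames must be matrices with identical dimensions")
    if (!all(is.finite(f)) || any(f < 0))
      stop("frame intensities must be finite and non-negative")
  }
  if (length(timestamps) != length(frames))
    stop("one timestamp per frame required")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a positive scalar (micrometres per pixel)")
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps),
         pixel_size = as.numeric(pixel_size)),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_stack: %d frames of %d x %d px, pixel size %.4g um\n",
              length(x$frames), d[1], d[2], x$pixel_size))
  cat(sprintf("  time span %.4g .. %.4g s\n",
              x$timestamps[1], x$timestamps[length(x$timestamps)]))
  invisible(x)
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Convert a raw frame to a single grayscale intensity field
#'
#' Multichannel (RGB) frames are reduced with the ITU-R BT.601 luminance
#' weights (0.299, 0.587, 0.114); already-grayscale input is returned
#' unchanged. A 3D array with a single channel slice is treated as
#' grayscale.
#'
#' @param raw_frame a numeric matrix (grayscale) or a 3D array with the
#'   channels in the third dimension.
#' @return A numeric matrix.
#' @export
to_grayscale <- function(raw_frame) {
  if (length(raw_frame) == 0L) stop("empty image")
  if (is.matrix(raw_frame)) return(raw_frame)
  if (!(is.array(raw_frame) && length(dim(raw_frame)) == 3L))
    stop("expected a matrix or a 3D channel array")
  d <- dim(raw_frame)
  if (d[3] == 1L) return(raw_frame[, , 1L])
  if (d[3] < 3L) stop("unsupported channel count: ", d[3])
  # BT.601 luma; a possible 4th (alpha) channel is ignored
  w <- c(0.299, 0.587, 0.114)
  w[1] * raw_frame[, , 1L] + w[2] * raw_frame[, , 2L] + w[3] * raw_frame[, , 3L]
}

#' Read a time-lapse stack from a multi-frame TIFF or a directory of PNGs
#'
#' Frames are converted to grayscale on read. For a directory, files
#' matching `*.png` are taken in lexicographic order.
#'
#' @param path a multi-frame TIFF file or a directory of numbered PNG
#'   frames.
#' @param frame_interval time between consecutive frames, seconds.
#' @param pixel_size micrometres per pixel.
#' @param t0 timestamp of the first frame, seconds (default 0).
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, frame_interval, pixel_size, t0 = 0) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no PNG frames found in ", path)
    raw <- lapply(files, png::readPNG)
  } else {
    raw <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(raw)) raw <- list(raw)
  }
  frames <- lapply(raw, to_grayscale)
  frame_stack(frames,
              timestamps = t0 + frame_interval * (seq_along(frames) - 1),
              pixel_size = pixel_size)
}

#' Write a frame stack to a multi-frame TIFF
#'
#' Intensities are rescaled to `[0, 1]` by the global stack maximum before
#' writing (TIFF stores normalized floats); the scale factor is returned
#' invisibly for round-trip use.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path.
#' @param bits_per_sample bit depth passed to [tiff::writeTIFF()].
#' @return Invisibly, the intensity scale factor used.
#' @export
write_frame_stack <- function(stack, path, bits_per_sample = 16L) {
  stopifnot(inherits(stack, "frame_stack"))
  mx <- max(1e-12, max(vapply(stack$frames, max, numeric(1))))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / mx), path,
                  bits.per.sample = bits_per_sample)
  invisible(mx)
}
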