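#' Hoshen-Kopelman cluster labeling of a binary occupancy grid
#'
#' Single-pass raster-scan connected-component labeling with union-find
#' (path-halving find, size-agnostic union), the standard algorithm of
#' percolation analysis. Supports 4- and 8-neighbor connectivity and
#' periodic (torus) boundaries; periodic labeling is used for lattice
#' simulation states, non-periodic for microscopy masks.
#'
#' @param mask a `binary_mask` from [segment_clusters()], or a logical
#'   matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edges + diagonals).
#'   Default 8, appropriate for blob-like image clusters; lattice states
#'   use 4.
#' @param periodic logical; if `TRUE`, clusters wrap across opposite
#'   edges.
#' @return An object of class `cluster_labeling`: list with `labels`
#'   (integer matrix; 0 = empty, k >= 1 = cluster id, ids forming a
#'   contiguous range 1..K in raster order of first appearance) and
#'   `sizes` (integer vector of per-cluster pixel counts).
#' @export
label_clusters <- function(mask, connectivity = 8, periodic = FALSE) {
  grid <- if (inherits(mask, "binary_mask")) mask$grid else mask
  if (!is.matrix(grid) || length(grid) == 0L)
    stop("'mask' must be a non-empty matrix")
  if (!is.logical(grid)) grid <- grid != 0
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")

  nr <- nrow(grid); nc <- ncol(grid)
  parent <- integer(nr * nc)  # 0 = unlabeled; else union-find parent slot
  lab <- matrix(0L, nr, nc)
  nlab <- 0L

  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  diag8 <- connectivity == 8
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!grid[i, j]) next
      # scan-order neighbors: up, left (+ two upper diagonals for 8-conn)
      roots <- integer(0)
      if (i > 1L && grid[i - 1L, j]) roots <- c(roots, lab[i - 1L, j])
      if (j > 1L && grid[i, j - 1L]) roots <- c(roots, lab[i, j - 1L])
      if (diag8 && i > 1L && j > 1L && grid[i - 1L, j - 1L])
        roots <- c(roots, lab[i - 1L, j - 1L])
      if (diag8 && i < nr && j > 1L && grid[i + 1L, j - 1L])
        roots <- c(roots, lab[i + 1L, j - 1L])
      if (length(roots) == 0L) {
        nlab <- nlab + 1L
        parent[nlab] <- nlab
        lab[i, j] <- nlab
      } else {
        r0 <- find(roots[1])
        for (r in roots[-1]) unite(r0, r)
        lab[i, j] <- find(r0)
      }
    }
  }

  if (periodic && nlab > 0L) {
    # merge across the wrapped seams (rows 1/nr, columns 1/nc)
    if (nr > 1L) for (j in seq_len(nc)) {
      if (grid[1L, j] && grid[nr, j]) unite(lab[1L, j], lab[nr, j])
      if (diag8 && grid[1L, j]) {
        jl <- if (j > 1L) j - 1L else nc
        jr <- if (j < nc) j + 1L else 1L
        if (grid[nr, jl]) unite(lab[1L, j], lab[nr, jl])
        if (grid[nr, jr]) unite(lab[1L, j], lab[nr, jr])
      }
    }
    if (nc > 1L) for (i in seq_len(nr)) {
      if (grid[i, 1L] && grid[i, nc]) unite(lab[i, 1L], lab[i, nc])
      if (diag8 && grid[i, 1L]) {
        iu <- if (i > 1L) i - 1L else nr
        id <- if (i < nr) i + 1L else 1L
        if (grid[iu, nc]) unite(lab[i, 1L], lab[iu, nc])
        if (grid[id, nc]) unite(lab[i, 1L], lab[id, nc])
      }
    }
  }

  # resolve provisional labels to roots, then compress ids to 1..K in
  # raster order of first appearance
  occ <- which(lab != 0L)
  if (length(occ)) {
    roots <- vapply(lab[occ], find, integer(1))
    ids <- match(roots, unique(roots))
    lab[occ] <- ids
    sizes <- tabulate(ids)
  } else {
    sizes <- integer(0)
  }
  structure(list(labels = lab, sizes = sizes), class = "cluster_labeling")
}

#' @export
print.cluster_labeling <- function(x, ...) {
  cat(sprintf("cluster_labeling: %d clusters over %d occupied pixels\n",
              length(x$sizes), sum(x$sizes)))
  invisible(x)
}

#' Per-cluster summary table of a labeled frame
#'
#' @param labeling a `cluster_labeling`.
#' @param pixel_size micrometres per pixel, for physical areas.
#' @return A data.frame with label, size in pixels, area in square
#'   micrometres, and centroid row/column (pixel coordinates).
#' @export
cluster_table <- function(labeling, pixel_size = 1) {
  stopifnot(inherits(labeling, "cluster_labeling"))
  k <- length(labeling$sizes)
  if (k == 0L)
    return(data.frame(label = integer(0), size_px = integer(0),
                      area_um2 = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0)))
  occ <- which(labeling$labels != 0L, arr.ind = TRUE)
  id <- labeling$labels[labeling$labels != 0L]
  data.frame(
    label = seq_len(k),
    size_px = labeling$sizes,
    area_um2 = labeling$sizes * pixel_size^2,
    centroid_row = as.numeric(tapply(occ[, 1], id, mean)),
    centroid_col = as.numeric(tapply(occ[, 2], id, mean)))
}
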