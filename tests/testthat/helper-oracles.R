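# Independent oracles used across the suite.

# Breadth-first flood-fill labeling, independent of the union-find
# implementation under test. Returns an integer label matrix with ids in
# column-major order of first appearance.
flood_fill_labels <- function(grid, connectivity = 4, periodic = FALSE) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  di <- c(-1L, 1L, 0L, 0L); dj <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    di <- c(di, -1L, -1L, 1L, 1L); dj <- c(dj, -1L, 1L, -1L, 1L)
  }
  neighbors <- function(idx) {
    i <- (idx - 1L) %% nr + 1L
    j <- (idx - 1L) %/% nr + 1L
    ii <- rep(i, times = length(di)) + rep(di, each = length(i))
    jj <- rep(j, times = length(dj)) + rep(dj, each = length(j))
    if (periodic) {
      ii <- (ii - 1L) %% nr + 1L
      jj <- (jj - 1L) %% nc + 1L
    }
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    unique((jj[ok] - 1L) * nr + ii[ok])
  }
  k <- 0L
  for (s in which(grid)) {
    if (lab[s] > 0L) next
    k <- k + 1L
    frontier <- s
    lab[s] <- k
    while (length(frontier)) {
      nb <- neighbors(frontier)
      nb <- nb[grid[nb] & lab[nb] == 0L]
      lab[nb] <- k
      frontier <- nb
    }
  }
  lab
}

# labelings agree up to a permutation of ids
expect_same_labeling <- function(lab1, lab2) {
  occ1 <- lab1 != 0L; occ2 <- lab2 != 0L
  expect_identical(occ1, occ2)
  norm <- function(v) match(v, unique(v))
  expect_identical(norm(lab1[occ1]), norm(lab2[occ2]))
}

# direct truncated-Gaussian 2D convolution with reflect padding; the
# brute-force counterpart of the separable implementation
direct_gaussian_smooth <- function(field, sigma, truncate = 4) {
  nr <- nrow(field); nc <- ncol(field)
  rr <- ceiling(truncate * sigma[1]); rc <- ceiling(truncate * sigma[2])
  kr <- stats::dnorm(-rr:rr, sd = sigma[1]); kr <- kr / sum(kr)
  kc <- stats::dnorm(-rc:rc, sd = sigma[2]); kc <- kc / sum(kc)
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 2L - i, i)
    pmin(pmax(ifelse(i > n, 2L * n - i, i), 1L), n)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in -rr:rr) for (b in -rc:rc) {
      acc <- acc + kr[a + rr + 1L] * kc[b + rc + 1L] *
        field[refl(i + a, nr), refl(j + b, nc)]
    }
    out[i, j] <- acc
  }
  out
}

# random binary mask fixture
random_mask <- function(nr, nc, occupancy) {
  matrix(runif(nr * nc) < occupancy, nr, nc)
}
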