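# Internal numeric helpers shared across modules.

# Sliding-window sum along one axis of a 3D array, window half-width h voxels,
# truncated (not padded) at the borders.
.slide_sum_axis <- function(a, axis, h) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  m <- matrix(ap, nrow = n)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(seq_len(n) + h, n)
  lo <- pmax(seq_len(n) - h, 1)
  out <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  aperm(array(out, dim = dim(ap)), order(perm))
}

# Number of in-bounds voxels in a truncated window of half-width h, per position.
.slide_count <- function(n, h) {
  pmin(seq_len(n) + h, n) - pmax(seq_len(n) - h, 1) + 1L
}

# Local mean over a box window given per-axis half-widths (truncated at borders).
# Axes with half-width 0 are untouched.
.local_mean <- function(a, half) {
  s <- a
  for (ax in 1:3) if (half[ax] > 0L) s <- .slide_sum_axis(s, ax, half[ax])
  d <- dim(a)
  cnt <- array(1, dim = d)
  counts <- lapply(1:3, function(ax) .slide_count(d[ax], half[ax]))
  cz <- counts[[1]]; cy <- counts[[2]]; cx <- counts[[3]]
  denom <- outer(outer(cz, cy), cx)
  s / denom
}

# Separable Gaussian blur with sigma given per axis in voxels; kernels are
# truncated at 4 sigma and renormalised so constants are preserved.
.gaussian_blur <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    g <- stats::dnorm(seq(-r, r), sd = s)
    n <- dim(a)[ax]
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      j <- idx + off
      ok <- j >= 1 & j <= n
      K[cbind(idx[ok], j[ok])] <- g[off + r + 1L]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- array(K %*% matrix(ap, nrow = dp[1]), dim = dp)
    a <- aperm(ap, order(perm))
  }
  a
}

# Run-length encode a sorted integer index vector into (start, length) pairs.
.rle_encode <- function(idx) {
  if (length(idx) == 0L) return(list(starts = integer(0), lengths = integer(0)))
  idx <- sort(as.integer(idx))
  brk <- c(TRUE, diff(idx) != 1L)
  starts <- idx[brk]
  lengths <- diff(c(which(brk), length(idx) + 1L))
  list(starts = starts, lengths = as.integer(lengths))
}

.rle_decode <- function(rle) {
  if (length(rle$starts) == 0L) return(integer(0))
  unlist(mapply(function(s, l) seq.int(s, length.out = l),
                rle$starts, rle$lengths, SIMPLIFY = FALSE), use.names = FALSE)
}

# Centroid (in um, axis order z,y,x) of a set of linear voxel indices.
.index_centroid_um <- function(idx, dim3, voxel_size) {
  sub <- arrayInd(idx, dim3)
  (colMeans(sub) - 0.5) * voxel_size
}

`%||%` <- function(a, b) if (is.null(a)) b else a
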