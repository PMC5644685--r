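# Internal array helpers shared by the texture and phantom code.

# Shift a 3D array by an integer offset d = (dx, dy, dz): the output at
# index i holds a[i + d]; positions whose source falls outside the grid
# become NA. Used for co-occurrence pairing, neighbourhood sums, sphere
# means and separable convolution.
shift_array <- function(a, d) {
  dims <- dim(a)
  out <- array(NA_real_, dims)
  rng_dst <- vector("list", 3L)
  rng_src <- vector("list", 3L)
  for (k in 1:3) {
    lo <- max(1L, 1L - d[k])
    hi <- min(dims[k], dims[k] - d[k])
    if (lo > hi) return(out)
    rng_dst[[k]] <- lo:hi
    rng_src[[k]] <- (lo + d[k]):(hi + d[k])
  }
  out[rng_dst[[1]], rng_dst[[2]], rng_dst[[3]]] <-
    a[rng_src[[1]], rng_src[[2]], rng_src[[3]]]
  out
}

# Embed quantized VOI levels into a dense array over the VOI bounding box,
# NA outside the VOI. coords are 0-based.
level_array <- function(levels, coords) {
  lo <- apply(coords, 2L, min)
  hi <- apply(coords, 2L, max)
  dims <- hi - lo + 1L
  arr <- array(NA_real_, dims)
  arr[cbind(coords[, 1] - lo[1] + 1L,
            coords[, 2] - lo[2] + 1L,
            coords[, 3] - lo[3] + 1L)] <- levels
  arr
}

# The 26 nonzero offsets at Chebyshev distance 1.
offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  as.matrix(g)
}

# The 13 unique direction offsets (one of each +/- pair).
offsets_13 <- function() {
  o <- offsets_26()
  keep <- o[, 3] > 0 |
    (o[, 3] == 0 & o[, 2] > 0) |
    (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0)
  o[keep, , drop = FALSE]
}

# Separable 3D Gaussian smoothing with per-axis sigma in voxels.
# Zero-padded boundaries; kernels truncated at 3 sigma and normalised.
gaussian_smooth_3d <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    out <- array(0, dim(a))
    for (j in seq_along(k)) {
      d <- integer(3L)
      d[axis] <- j - r - 1L
      sh <- shift_array(a, d)
      sh[is.na(sh)] <- 0
      out <- out + k[j] * sh
    }
    a <- out
  }
  a
}
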