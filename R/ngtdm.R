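#' Build the neighbourhood grey-tone difference matrix of a quantized VOI
#'
#' Amadasun-King NGTDM with the original complete-neighbourhood rule in
#' 3D: the neighbourhood of a voxel is its 26-connected shell (adjacent
#' voxels in the same and adjacent planes, distance 1 in index space
#' regardless of anisotropic spacing), and only VOI voxels whose full
#' 26-neighbourhood lies inside the VOI contribute. For each grey level
#' `i`, `s[i]` sums `|i - Abar|` over contributing voxels of level `i`,
#' where `Abar` is the mean level of the 26 neighbours; `n[i]` counts the
#' contributing voxels and `p[i] = n[i] / sum(n)`.
#'
#' @param quant a `quantized_voi`.
#' @return An object of class `pet_ngtdm`: list with vectors `s`, `n`,
#'   `p` (length Ng), `n_bins` and `n_valid = sum(n)`. A VOI thinner than
#'   3 voxels in any axis has no complete neighbourhood: `n_valid = 0`
#'   and the NGTDM features are reported missing.
#' @export
build_ngtdm <- function(quant) {
  stopifnot(inherits(quant, "quantized_voi"))
  ng <- quant$n_bins
  arr <- level_array(quant$levels, quant$coords)
  offs <- offsets_26()
  nbr_sum <- array(0, dim(arr))
  complete <- array(TRUE, dim(arr))
  for (i in seq_len(nrow(offs))) {
    sh <- shift_array(arr, offs[i, ])
    complete <- complete & !is.na(sh)
    sh[is.na(sh)] <- 0
    nbr_sum <- nbr_sum + sh
  }
  use <- !is.na(arr) & complete
  s <- numeric(ng)
  n <- integer(ng)
  n_valid <- sum(use)
  if (n_valid > 0) {
    lv <- arr[use]
    dev <- abs(lv - nbr_sum[use] / 26)
    n <- tabulate(lv, nbins = ng)
    agg <- rowsum(dev, lv)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  p <- if (n_valid > 0) n / n_valid else numeric(ng)
  structure(
    list(s = s, n = n, p = p, n_bins = ng, n_valid = n_valid),
    class = "pet_ngtdm"
  )
}

#' @export
print.pet_ngtdm <- function(x, ...) {
  cat(sprintf("<pet_ngtdm> Ng = %d, %d voxels with complete neighbourhood, %d levels present\n",
              x$n_bins, x$n_valid, sum(x$p > 0)))
  invisible(x)
}

#' High-order (NGTDM) texture features
#'
#' Amadasun-King statistics over the levels present in the matrix
#' (`p[i] > 0`), with `N = sum(n)` voxels and `G` present levels:
#' \itemize{
#'   \item coarseness: `1 / (eps + sum(p * s))`; `eps` (default 1e-6)
#'     caps the value for perfectly flat textures at `1/eps`.
#'   \item contrast:
#'     `(sum_{i,j} p_i p_j (i-j)^2 / (G (G-1))) * (sum(s) / N)`;
#'     0 by convention when `G = 1`.
#'   \item busyness: `sum(p * s) / sum_{i,j} |i p_i - j p_j|` over
#'     present pairs; missing when the denominator is 0.
#'   \item complexity:
#'     `(1/N) * sum_{i,j} (|i-j| / (p_i + p_j)) * (p_i s_i + p_j s_j)`
#'     over present pairs.
#' }
#'
#' @param ngtdm a `pet_ngtdm` from [build_ngtdm()].
#' @param epsilon coarseness regulariser.
#' @return A one-row tibble with `ngtdm_coarseness`, `ngtdm_contrast`,
#'   `ngtdm_busyness`, `ngtdm_complexity`; all `NA` when no voxel had a
#'   complete neighbourhood.
#' @export
ngtdm_features <- function(ngtdm, epsilon = 1e-6) {
  stopifnot(inherits(ngtdm, "pet_ngtdm"))
  if (ngtdm$n_valid == 0) {
    return(tibble::tibble(ngtdm_coarseness = NA_real_,
                          ngtdm_contrast = NA_real_,
                          ngtdm_busyness = NA_real_,
                          ngtdm_complexity = NA_real_))
  }
  present <- which(ngtdm$p > 0)
  g <- length(present)
  n_total <- ngtdm$n_valid
  p <- ngtdm$p[present]
  s <- ngtdm$s[present]
  lev <- present
  ps <- sum(p * s)

  coarseness <- 1 / (epsilon + ps)

  contrast <- if (g > 1) {
    dif2 <- outer(lev, lev, `-`)^2
    (sum(outer(p, p) * dif2) / (g * (g - 1))) * (sum(ngtdm$s) / n_total)
  } else {
    0
  }

  ip <- lev * p
  busy_den <- sum(abs(outer(ip, ip, `-`)))
  busyness <- if (busy_den > 0) ps / busy_den else NA_real_

  dif <- abs(outer(lev, lev, `-`))
  psum <- outer(p, p, `+`)
  cross <- outer(p * s, p * s, `+`)
  complexity <- sum(dif / psum * cross) / n_total

  tibble::tibble(
    ngtdm_coarseness = coarseness,
    ngtdm_contrast = contrast,
    ngtdm_busyness = busyness,
    ngtdm_complexity = complexity
  )
}
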