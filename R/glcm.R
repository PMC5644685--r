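#' Build the grey-level co-occurrence matrix of a quantized VOI
#'
#' Counts grey-level co-occurrences between voxel pairs at Chebyshev
#' distance 1 in 3D, over all 13 unique direction offsets, with both
#' voxels required to lie inside the VOI. Counts from all directions are
#' merged into a single matrix before normalisation, and each pair is
#' counted in both orders, so the matrix is symmetric by construction.
#'
#' @param quant a `quantized_voi`.
#' @return An object of class `pet_glcm`: list with `p` (Ng x Ng
#'   probability matrix summing to 1 when pairs exist), `pair_count`
#'   (total ordered pairs counted), `n_bins`, `offsets` (the 13
#'   displacement vectors). A VOI with no valid pair (e.g. a single
#'   isolated voxel) yields `pair_count = 0` and an all-zero `p`; GLCM
#'   features are then reported missing.
#' @export
build_glcm <- function(quant) {
  stopifnot(inherits(quant, "quantized_voi"))
  ng <- quant$n_bins
  arr <- level_array(quant$levels, quant$coords)
  offs <- offsets_13()
  counts <- matrix(0, ng, ng)
  for (i in seq_len(nrow(offs))) {
    sh <- shift_array(arr, offs[i, ])
    ok <- !is.na(arr) & !is.na(sh)
    if (!any(ok)) next
    idx <- (arr[ok] - 1) * ng + sh[ok]
    tab <- tabulate(idx, nbins = ng * ng)
    counts <- counts + matrix(tab, ng, ng, byrow = TRUE)
  }
  counts <- counts + t(counts)  # both orders of each pair
  pair_count <- sum(counts)
  p <- if (pair_count > 0) counts / pair_count else counts
  structure(
    list(p = p, pair_count = pair_count, n_bins = ng, offsets = offs),
    class = "pet_glcm"
  )
}

#' @export
print.pet_glcm <- function(x, ...) {
  cat(sprintf("<pet_glcm> %d x %d, %d voxel pairs, %d nonzero cells\n",
              x$n_bins, x$n_bins, x$pair_count, sum(x$p > 0)))
  invisible(x)
}

#' Second-order (GLCM) texture features
#'
#' Haralick-style statistics of the co-occurrence probabilities `p[i, j]`:
#' \itemize{
#'   \item contrast: `sum (i - j)^2 * p[i, j]`
#'   \item entropy: `-sum p * log2(p)` in bits (zero cells skipped)
#'   \item uniformity (angular second moment): `sum p^2`
#'   \item homogeneity (inverse difference moment):
#'     `sum p / (1 + (i - j)^2)`
#' }
#'
#' @param glcm a `pet_glcm` from [build_glcm()].
#' @return A one-row tibble with `glcm_contrast`, `glcm_entropy`,
#'   `glcm_uniformity`, `glcm_homogeneity`; all `NA` when the VOI had no
#'   co-occurring pair (missing, never imputed as 0).
#' @export
glcm_features <- function(glcm) {
  stopifnot(inherits(glcm, "pet_glcm"))
  if (glcm$pair_count == 0) {
    return(tibble::tibble(glcm_contrast = NA_real_, glcm_entropy = NA_real_,
                          glcm_uniformity = NA_real_,
                          glcm_homogeneity = NA_real_))
  }
  p <- glcm$p
  ng <- glcm$n_bins
  dif <- outer(seq_len(ng), seq_len(ng), `-`)
  pp <- p[p > 0]
  tibble::tibble(
    glcm_contrast = sum(dif^2 * p),
    glcm_entropy = -sum(pp * log2(pp)),
    glcm_uniformity = sum(p^2),
    glcm_homogeneity = sum(p / (1 + dif^2))
  )
}
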