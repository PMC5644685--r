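#' Quantize VOI intensities to discrete grey levels
#'
#' Fixed-bin-number min-max binning over the VOI voxels only:
#' `level(v) = min(Ng, 1 + floor(Ng * (v - v_min) / (v_max - v_min)))`,
#' with `v_min`/`v_max` the VOI minimum and maximum. The top edge is
#' closed, so `v_max` maps to level `Ng`. A constant VOI maps every voxel
#' to level 1. Because the bin edges are taken from the VOI's own range,
#' the level assignment is invariant under any strictly increasing affine
#' rescaling of the intensities.
#'
#' @param sample a `voi_sample` from [extract_voi()].
#' @param n_bins number of grey levels Ng (>= 2); the analysis default
#'   is 64.
#' @return An object of class `quantized_voi`: list with integer `levels`
#'   in 1..Ng, `coords`, `n_bins`, `v_min`, `v_max`.
#' @export
quantize_voi <- function(sample, n_bins = 64L) {
  stopifnot(inherits(sample, "voi_sample"))
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) {
    stop("`n_bins` must be an integer >= 2", call. = FALSE)
  }
  v <- sample$values
  v_min <- min(v)
  v_max <- max(v)
  if (v_max > v_min) {
    lev <- pmin(n_bins, 1L + floor(n_bins * (v - v_min) / (v_max - v_min)))
  } else {
    lev <- rep(1L, length(v))
  }
  structure(
    list(levels = as.integer(lev), coords = sample$coords,
         n_bins = n_bins, v_min = v_min, v_max = v_max),
    class = "quantized_voi"
  )
}

#' @export
print.quantized_voi <- function(x, ...) {
  cat(sprintf(
    "<quantized_voi> %d voxels, Ng = %d, SUV range [%.4g, %.4g], %d levels occupied\n",
    length(x$levels), x$n_bins, x$v_min, x$v_max, length(unique(x$levels))))
  invisible(x)
}
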