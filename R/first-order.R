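#' First-order (histogram) features of a VOI
#'
#' SUV statistics are computed on the raw SUV values; entropy and
#' uniformity on the quantized grey-level histogram. With `h_l` the
#' fraction of VOI voxels at level `l`:
#' \itemize{
#'   \item `sd` — population standard deviation (divide by n) of the SUV
#'     values;
#'   \item `fo_entropy` — `-sum h_l * log2(h_l)` in bits, zero-frequency
#'     terms skipped;
#'   \item `fo_uniformity` — `sum h_l^2` (also called energy), in (0, 1].
#' }
#'
#' @param sample a `voi_sample`; must describe the same voxels as `quant`.
#' @param quant the matching `quantized_voi`.
#' @return A one-row tibble with `suv_max`, `suv_mean`, `sd`,
#'   `fo_entropy`, `fo_uniformity`.
#' @export
first_order_features <- function(sample, quant) {
  stopifnot(inherits(sample, "voi_sample"), inherits(quant, "quantized_voi"))
  if (length(sample$values) != length(quant$levels)) {
    stop("`sample` and `quant` describe different voxel sets", call. = FALSE)
  }
  v <- sample$values
  h <- tabulate(quant$levels, nbins = quant$n_bins) / length(quant$levels)
  h <- h[h > 0]
  tibble::tibble(
    suv_max = max(v),
    suv_mean = mean(v),
    sd = sqrt(mean((v - mean(v))^2)),
    fo_entropy = -sum(h * log2(h)),
    fo_uniformity = sum(h^2)
  )
}

# Integer offsets whose voxel-centre distance is within a sphere of the
# given volume (ml) at the given spacing (mm).
sphere_offsets <- function(spacing, volume_ml = 1.0) {
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  half <- floor(r / spacing + 1e-9)
  g <- as.matrix(expand.grid(dx = -half[1]:half[1],
                             dy = -half[2]:half[2],
                             dz = -half[3]:half[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2
  g[d2 <= r^2 + 1e-9, , drop = FALSE]
}

#' SUVpeak: maximum local 1 ml spherical mean
#'
#' For every VOI voxel, averages the SUV over a sphere of the given
#' volume (default 1.0 ml, radius 6.2 mm) centred on that voxel; returns
#' the maximum over the VOI. Sphere membership is decided by
#' voxel-centre distance in physical mm, so the sphere is anisotropic in
#' index space. Sphere voxels falling outside the image grid are
#' excluded from the mean (the local mean is taken over the in-image
#' part of the sphere); sphere voxels outside the VOI but inside the
#' image do contribute, matching the usual SUVpeak convention in which
#' only the sphere centre is constrained to the lesion.
#'
#' @param volume a `pet_volume` in SUV units.
#' @param mask a non-empty `pet_mask` on the same grid.
#' @param volume_ml sphere volume in ml.
#' @return The SUVpeak value (scalar).
#' @export
suv_peak <- function(volume, mask, volume_ml = 1.0) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "pet_mask"))
  if (!identical(dim(mask$flags), dim(volume$values))) {
    stop("mask and volume shapes differ", call. = FALSE)
  }
  if (!any(mask$flags)) {
    stop("mask is empty", call. = FALSE)
  }
  offs <- sphere_offsets(volume$spacing, volume_ml)
  acc <- array(0, dim(volume$values))
  cnt <- array(0, dim(volume$values))
  for (i in seq_len(nrow(offs))) {
    sh <- shift_array(volume$values, offs[i, ])
    inside <- !is.na(sh)
    sh[!inside] <- 0
    acc <- acc + sh
    cnt <- cnt + inside
  }
  peak_field <- acc / cnt
  max(peak_field[mask$flags])
}
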