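#' Names of the per-lesion heterogeneity parameters
#'
#' The 15 parameters computed per lesion per timepoint, in report order:
#' three SUV parameters, three other first-order parameters, four GLCM
#' (second-order) parameters, four NGTDM (high-order) parameters, and
#' the combined ratio SUVmax / NGTDM contrast.
#'
#' @return Character vector of length 15.
#' @export
feature_names <- function() {
  c("suv_max", "suv_mean", "suv_peak", "sd", "fo_entropy", "fo_uniformity",
    "glcm_contrast", "glcm_entropy", "glcm_uniformity", "glcm_homogeneity",
    "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness",
    "ngtdm_complexity", "suvmax_ngtdm_contrast_ratio")
}

#' Combined parameter SUVmax / NGTDM contrast
#'
#' @param suv_max SUVmax of the lesion.
#' @param ngtdm_contrast NGTDM contrast of the lesion.
#' @return The ratio, or `NA` when the contrast is missing or zero
#'   (missing features propagate, they are never imputed).
#' @export
combined_ratio <- function(suv_max, ngtdm_contrast) {
  dplyr::if_else(
    is.na(ngtdm_contrast) | ngtdm_contrast == 0,
    NA_real_,
    suv_max / ngtdm_contrast
  )
}

#' Extract all heterogeneity parameters from one lesion
#'
#' Orchestrates the full per-lesion feature computation: VOI extraction,
#' 64-level min-max quantization, first-order statistics, SUVpeak, GLCM
#' construction and features, NGTDM construction and features, and the
#' combined SUVmax / NGTDM contrast ratio. Undefined features (NGTDM on a
#' VOI with no complete 26-neighbourhood, busyness with a zero
#' denominator, the combined ratio when NGTDM contrast is 0) are returned
#' as `NA`.
#'
#' @param volume a `pet_volume` in SUV units.
#' @param mask a non-empty `pet_mask` on the same grid.
#' @param n_bins number of grey levels for quantization (default 64).
#' @param peak_volume_ml SUVpeak sphere volume in ml (default 1.0).
#' @param ngtdm_epsilon coarseness regulariser (default 1e-6).
#' @return A one-row tibble: the 15 columns of [feature_names()] plus
#'   `n_voxels` and `voi_ml`.
#' @export
extract_features <- function(volume, mask, n_bins = 64L,
                             peak_volume_ml = 1.0, ngtdm_epsilon = 1e-6) {
  sample <- extract_voi(volume, mask)
  quant <- quantize_voi(sample, n_bins)
  fo <- first_order_features(sample, quant)
  peak <- suv_peak(volume, mask, peak_volume_ml)
  glcm <- glcm_features(build_glcm(quant))
  ngtdm <- ngtdm_features(build_ngtdm(quant), ngtdm_epsilon)
  dplyr::bind_cols(
    fo[, c("suv_max", "suv_mean")],
    tibble::tibble(suv_peak = peak),
    fo[, c("sd", "fo_entropy", "fo_uniformity")],
    glcm,
    ngtdm,
    tibble::tibble(
      suvmax_ngtdm_contrast_ratio =
        combined_ratio(fo$suv_max, ngtdm$ngtdm_contrast),
      n_voxels = length(sample$values),
      voi_ml = voi_volume_ml(sample)
    )
  )
}
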