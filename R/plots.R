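#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the empirical ROC curve of a fitted AUROC
#'
#' @param object a `pet_roc` from [roc_auc()].
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.pet_roc <- function(object, ...) {
  s <- object$scores
  mal <- object$malignant
  cuts <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(cuts, function(ct) {
    tibble::tibble(
      fpr = mean(s[!mal] >= ct),
      tpr = mean(s[mal] >= ct)
    )
  })
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUROC %.3f (%d%% CI %.3f-%.3f)",
                      object$auroc, round(100 * object$conf_level),
                      object$ci_low, object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Boxplots of features by class and timepoint
#'
#' @param features a feature tibble from [cohort_features()].
#' @param which feature names to show (default: the three SUV
#'   parameters and the three other first-order parameters).
#' @return A ggplot, faceted by feature with free y scales.
#' @export
plot_feature_distributions <- function(features,
                                       which = c("suv_max", "suv_mean",
                                                 "suv_peak", "sd",
                                                 "fo_entropy",
                                                 "fo_uniformity")) {
  long <- features_long(features) |>
    dplyr::filter(.data$feature %in% which, is.finite(.data$value))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$timepoint, y = .data$value,
                               fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Value", fill = NULL) +
    ggplot2::theme_minimal()
}
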