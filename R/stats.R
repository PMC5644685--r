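#' Mann-Whitney U test between two groups
#'
#' Rank-sum test with midrank ties. The two-sided p value is computed by
#' exact enumeration when the pooled sample size is at most 12 and there
#' are no ties, and otherwise by the normal approximation with
#' tie-corrected variance and continuity correction (via
#' [stats::wilcox.test()]). Missing values are dropped.
#'
#' @param x,y numeric samples; each must contain at least one finite
#'   value after missing-value removal.
#' @return One-row tibble: `statistic` (U for `x` vs `y`), `p_value`,
#'   `n_x`, `n_y`, `method`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) == 0L || length(y) == 0L) {
    stop("each sample needs at least one finite value", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y) <= 12L)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_x = length(x),
    n_y = length(y),
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; two-sided p value via the
#' t-distribution approximation ([stats::cor.test()] with
#' `method = "spearman"`, `exact = FALSE`). Incomplete pairs are dropped.
#'
#' @param x,y paired numeric vectors; at least 3 complete pairs.
#' @return One-row tibble: `rho`, `p_value`, `n`. `rho` is `NA` when
#'   either variable has zero rank variance.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          n = length(x)))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

# Normalise a label vector to logical is-malignant. Accepts
# benign/malignant strings, factors, or logicals.
as_malignant <- function(labels) {
  if (is.logical(labels)) return(labels)
  lab <- tolower(as.character(labels))
  if (!all(lab %in% c("benign", "malignant"))) {
    stop("labels must be 'benign'/'malignant' (or logical is-malignant)",
         call. = FALSE)
  }
  lab == "malignant"
}

# DeLong structural components for oriented scores (higher = malignant).
# Returns list(auc, v10 (per malignant subject), v01 (per benign)).
delong_components <- function(pos, neg) {
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' Empirical AUROC with DeLong variance and confidence interval
#'
#' The area under the ROC curve is computed by the Mann-Whitney identity
#' (ties counted 1/2): it equals the probability that a random malignant
#' case scores above a random benign case. Variance and the Wald 95% CI
#' come from DeLong's structural-components estimator. With
#' `direction = "auto"` (default) the orientation is chosen so that the
#' reported AUROC is at least 0.5: `greater_is_malignant` unless the
#' feature is lower in malignant lesions.
#'
#' @param scores numeric scores; missing scores are dropped with their
#'   labels.
#' @param labels benign/malignant labels (or logical is-malignant);
#'   both classes must be present.
#' @param direction `"auto"`, `"greater"` (higher score = malignant) or
#'   `"lesser"`.
#' @param conf_level confidence level for the CI (default 0.95).
#' @return An object of class `pet_roc` with fields `auroc`, `ci_low`,
#'   `ci_high`, `variance`, `direction`, `n_benign`, `n_malignant`, and
#'   the structural components. Use [generics::tidy()] for a tibble.
#' @export
roc_auc <- function(scores, labels, direction = c("auto", "greater", "lesser"),
                    conf_level = 0.95) {
  direction <- match.arg(direction)
  mal <- as_malignant(labels)
  ok <- is.finite(scores) & !is.na(mal)
  scores <- scores[ok]
  mal <- mal[ok]
  if (!any(mal) || all(mal)) {
    stop("both classes must be present to compute an AUROC", call. = FALSE)
  }
  if (direction == "auto") {
    auc_greater <- delong_components(scores[mal], scores[!mal])$auc
    direction <- if (auc_greater >= 0.5) "greater" else "lesser"
  }
  oriented <- if (direction == "greater") scores else -scores
  comp <- delong_components(oriented[mal], oriented[!mal])
  m <- sum(mal)
  n <- sum(!mal)
  variance <- if (m > 1 && n > 1) {
    stats::var(comp$v10) / m + stats::var(comp$v01) / n
  } else {
    NA_real_
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- if (is.na(variance)) NA_real_ else z * sqrt(variance)
  structure(
    list(
      auroc = comp$auc,
      ci_low = if (is.na(half)) NA_real_ else max(0, comp$auc - half),
      ci_high = if (is.na(half)) NA_real_ else min(1, comp$auc + half),
      variance = variance,
      conf_level = conf_level,
      direction = paste0(direction, "_is_malignant"),
      n_benign = n,
      n_malignant = m,
      v10 = comp$v10,
      v01 = comp$v01,
      scores = oriented,
      malignant = mal
    ),
    class = "pet_roc"
  )
}

#' @export
print.pet_roc <- function(x, ...) {
  cat(sprintf("<pet_roc> AUROC %.3f (%d%% CI %.3f-%.3f), %s, n = %d benign / %d malignant\n",
              x$auroc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$direction, x$n_benign, x$n_malignant))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pet_roc <- function(x, ...) {
  tibble::tibble(
    auroc = x$auroc, ci_low = x$ci_low, ci_high = x$ci_high,
    variance = x$variance, direction = x$direction,
    n_benign = x$n_benign, n_malignant = x$n_malignant
  )
}

#' @export
glance.pet_roc <- function(x, ...) {
  tibble::tibble(
    auroc = x$auroc, variance = x$variance, conf_level = x$conf_level,
    n = x$n_benign + x$n_malignant, method = "delong"
  )
}

#' Paired DeLong comparison of two AUROCs
#'
#' Compares the AUROCs of two scores measured on the same subjects using
#' DeLong's paired test: `z = dAUC / sqrt(var_a + var_b - 2 cov)`, with
#' variances and the covariance estimated from the structural
#' components, and a two-sided normal p value. Each score is oriented
#' per its own `direction` argument (default `"auto"`, AUROC >= 0.5)
#' before comparison. Subjects with a missing value in either score are
#' dropped pairwise.
#'
#' @param scores_a,scores_b paired scores on the same subjects.
#' @param labels benign/malignant labels.
#' @param direction_a,direction_b orientation passed to [roc_auc()].
#' @return One-row tibble: `auroc_a`, `auroc_b`, `delta_auroc`,
#'   `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           direction_a = "auto", direction_b = "auto") {
  if (length(scores_a) != length(scores_b)) {
    stop("paired scores must have equal length", call. = FALSE)
  }
  mal <- as_malignant(labels)
  ok <- is.finite(scores_a) & is.finite(scores_b) & !is.na(mal)
  ra <- roc_auc(scores_a[ok], mal[ok], direction = direction_a)
  rb <- roc_auc(scores_b[ok], mal[ok], direction = direction_b)
  m <- ra$n_malignant
  n <- ra$n_benign
  cov_ab <- stats::cov(ra$v10, rb$v10) / m + stats::cov(ra$v01, rb$v01) / n
  delta <- ra$auroc - rb$auroc
  var_delta <- ra$variance + rb$variance - 2 * cov_ab
  if (!is.finite(var_delta) || var_delta <= 1e-15) {
    p <- if (abs(delta) < 1e-12) 1 else 0
    z <- if (abs(delta) < 1e-12) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(
    auroc_a = ra$auroc, auroc_b = rb$auroc, delta_auroc = delta,
    z = z, p_value = p
  )
}

#' Diagnostic metrics at the Youden-optimal cutoff
#'
#' Scans all midpoints between adjacent distinct score values (after
#' orienting so that higher = malignant), picks the cutoff maximising
#' the Youden index (sensitivity + specificity - 1), breaking ties
#' toward higher specificity (and then toward the higher cutoff), and
#' reports sensitivity, specificity, positive and negative predictive
#' value and accuracy at that cutoff. A lesion is called malignant when
#' its oriented score exceeds the cutoff.
#'
#' @inheritParams roc_auc
#' @return One-row tibble: `cutoff` (on the original score scale;
#'   interpret as "malignant if score < cutoff" when
#'   `direction == "lesser_is_malignant"`), `direction`, `youden`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
youden_metrics <- function(scores, labels,
                           direction = c("auto", "greater", "lesser")) {
  direction <- match.arg(direction)
  mal <- as_malignant(labels)
  ok <- is.finite(scores) & !is.na(mal)
  scores <- scores[ok]
  mal <- mal[ok]
  if (!any(mal) || all(mal)) {
    stop("both classes must be present", call. = FALSE)
  }
  if (direction == "auto") {
    auc_greater <- delong_components(scores[mal], scores[!mal])$auc
    direction <- if (auc_greater >= 0.5) "greater" else "lesser"
  }
  s <- if (direction == "greater") scores else -scores
  u <- sort(unique(s))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  best <- NULL
  for (cutoff in cand) {
    pred <- s > cutoff
    tp <- sum(pred & mal)
    fn <- sum(!pred & mal)
    tn <- sum(!pred & !mal)
    fp <- sum(pred & !mal)
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
      best <- list(cutoff = cutoff, j = j, sens = sens, spec = spec,
                   tp = tp, fp = fp, tn = tn, fn = fn)
    }
  }
  tibble::tibble(
    cutoff = if (direction == "greater") best$cutoff else -best$cutoff,
    direction = paste0(direction, "_is_malignant"),
    youden = best$j,
    sensitivity = best$sens,
    specificity = best$spec,
    ppv = if (best$tp + best$fp > 0) best$tp / (best$tp + best$fp) else NA_real_,
    npv = if (best$tn + best$fn > 0) best$tn / (best$tn + best$fn) else NA_real_,
    accuracy = (best$tp + best$tn) / length(s)
  )
}

#' Intraclass correlation for two-rater agreement
#'
#' Two-way random-effects, single-measures ICC. The default form is
#' absolute agreement, ICC(2,1):
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))`, with
#' `MS_R`, `MS_C`, `MS_E` the subject, rater and residual mean squares
#' of the two-way ANOVA. The 95% CI uses the F-distribution method.
#' Identical raters give ICC = 1 exactly.
#'
#' @param ratings numeric matrix or data frame, subjects in rows, exactly
#'   2 rater columns, complete (no missing cells); at least 5 subjects.
#' @param form `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)-style consistency under the two-way model).
#' @param conf_level confidence level.
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `form`,
#'   `n_subjects`, `n_raters`.
#' @export
icc_agreement <- function(ratings, form = c("agreement", "consistency"),
                          conf_level = 0.95) {
  form <- match.arg(form)
  x <- as.matrix(ratings)
  if (ncol(x) != 2L) {
    stop("`ratings` must have exactly 2 rater columns", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("`ratings` must be complete (no missing cells)", call. = FALSE)
  }
  n <- nrow(x)
  if (n < 5L) {
    stop("need at least 5 subjects", call. = FALSE)
  }
  k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    # all variance is between subjects: perfect agreement
    icc <- if (msr > 0) 1 else NA_real_
    lo <- hi <- icc
  } else if (form == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    # McGraw & Wong F-based interval for ICC(A,1)
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    f_l <- f_obs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_u <- f_obs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (f_l - 1) / (f_l + k - 1)
    hi <- (f_u - 1) / (f_u + k - 1)
  }
  tibble::tibble(
    icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc),
    form = form, n_subjects = n, n_raters = k
  )
}

#' Percentage change between early and late values
#'
#' `100 * (late - early) / early`; missing when the early value is 0 or
#' either value is missing. The sign convention (late minus early over
#' early) is a documented package choice.
#'
#' @param early,late numeric vectors of equal length.
#' @return Numeric vector of percentages.
#' @export
percent_change <- function(early, late) {
  stopifnot(length(early) == length(late))
  out <- 100 * (late - early) / early
  out[!is.finite(out) | is.na(early) | is.na(late) | early == 0] <- NA_real_
  out
}
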