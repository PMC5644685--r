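test_that("Mann-Whitney matches exact enumeration on separated samples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2 of the 20 label assignments as extreme
  expect_equal(r$method, "exact")
})

test_that("Mann-Whitney is symmetric and null on identical samples", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.7, 4.4)
  expect_equal(mann_whitney(x, x)$p_value, 1, tolerance = 0.05)
  y <- x + 0.8
  expect_equal(mann_whitney(x, y)$p_value, mann_whitney(y, x)$p_value)
  expect_error(mann_whitney(numeric(0), x), "at least one")
})

test_that("Spearman correlation matches the rank formula", {
  expect_equal(spearman_cor(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_cor(1:6, -(1:6)^3)$rho, -1)
  # n = 4, d = (1,-1,1,-1), sum d^2 = 4: rho = 1 - 6*4/(4*15) = 0.6
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  expect_true(is.na(spearman_cor(rep(1, 5), 1:5)$rho))
  expect_error(spearman_cor(1:2, 2:3), "3 complete")
})

test_that("AUROC handles separation, ties and the pairwise identity", {
  sep <- roc_auc(c(1, 2, 3, 10, 11, 12),
                 c("benign", "benign", "benign",
                   "malignant", "malignant", "malignant"))
  expect_equal(sep$auroc, 1.0)

  tied <- roc_auc(rep(2, 8), rep(c("benign", "malignant"), 4))
  expect_equal(tied$auroc, 0.5)

  r <- roc_auc(c(1, 2, 3, 4), c("benign", "malignant", "benign", "malignant"))
  expect_equal(r$auroc, 0.75)  # 3 concordant of 4 pairs

  expect_error(roc_auc(1:4, rep("benign", 4)), "both classes")
})

test_that("AUROC equals the tie-aware U statistic over n1*n2", {
  set.seed(41)
  for (i in 1:50) {
    n_b <- sample(3:15, 1)
    n_m <- sample(3:15, 1)
    scores <- c(sample(1:6, n_b, replace = TRUE) + rnorm(n_b, 0, 0.01) *
                  rbinom(n_b, 1, 0.5),
                sample(2:8, n_m, replace = TRUE))
    labels <- c(rep("benign", n_b), rep("malignant", n_m))
    r <- roc_auc(scores, labels, direction = "greater")
    # U for malignant vs benign from the rank-sum machinery
    u <- suppressWarnings(stats::wilcox.test(
      scores[labels == "malignant"], scores[labels == "benign"],
      exact = FALSE))$statistic
    expect_equal(r$auroc, unname(u) / (n_b * n_m), tolerance = 1e-12)
    expect_equal(r$auroc,
                 oracle_auc(scores, labels == "malignant"),
                 tolerance = 1e-12)
  }
})

test_that("auto direction reports AUROC of at least one half", {
  set.seed(43)
  scores <- c(rnorm(10, 3), rnorm(8, 1))  # malignant lower
  labels <- c(rep("benign", 10), rep("malignant", 8))
  r <- roc_auc(scores, labels)
  expect_gte(r$auroc, 0.5)
  expect_equal(r$direction, "lesser_is_malignant")
  forced <- roc_auc(scores, labels, direction = "greater")
  expect_equal(forced$auroc, 1 - r$auroc)
})

test_that("DeLong AUROC and CI agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(47)
  for (i in 1:10) {
    scores <- c(rnorm(20, 0), rnorm(15, 1.2))
    labels <- c(rep("benign", 20), rep("malignant", 15))
    r <- roc_auc(scores, labels, direction = "greater")
    pr <- pROC::roc(labels, scores, levels = c("benign", "malignant"),
                    direction = "<", quiet = TRUE)
    ci <- pROC::ci.auc(pr, method = "delong")
    expect_equal(r$auroc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$ci_low, ci[1], tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(r$ci_high, ci[3], tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("paired DeLong comparison agrees with pROC and its identities", {
  skip_if_not_installed("pROC")
  set.seed(53)
  n_b <- 30; n_m <- 24
  labels <- c(rep("benign", n_b), rep("malignant", n_m))
  base <- c(rnorm(n_b, 0), rnorm(n_m, 1))
  other <- 0.6 * base + sqrt(1 - 0.36) * rnorm(n_b + n_m)

  self <- delong_compare(base, base, labels)
  expect_equal(self$delta_auroc, 0)
  expect_equal(self$p_value, 1)

  cmp <- delong_compare(base, other, labels,
                        direction_a = "greater", direction_b = "greater")
  pr_a <- pROC::roc(labels, base, levels = c("benign", "malignant"),
                    direction = "<", quiet = TRUE)
  pr_b <- pROC::roc(labels, other, levels = c("benign", "malignant"),
                    direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(pr_a, pr_b, method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-9)

  # direction flip on separable data: maximal |delta|, tiny p
  sep <- c(rnorm(n_b, 0, 0.2), rnorm(n_m, 5, 0.2))
  flip <- delong_compare(sep, -sep, labels,
                         direction_a = "greater", direction_b = "greater")
  expect_equal(abs(flip$delta_auroc), 1)
  expect_lt(flip$p_value, 1e-6)
})

test_that("DeLong variance of the AUROC difference tracks a stratified bootstrap", {
  set.seed(59)
  n_b <- 30; n_m <- 24
  labels <- c(rep("benign", n_b), rep("malignant", n_m))
  a <- c(rnorm(n_b, 0), rnorm(n_m, 1.2))
  b <- 0.5 * a + sqrt(0.75) * rnorm(n_b + n_m)
  cmp <- delong_compare(a, b, labels,
                        direction_a = "greater", direction_b = "greater")
  var_delong <- (cmp$delta_auroc / cmp$z)^2

  idx_b <- which(labels == "benign")
  idx_m <- which(labels == "malignant")
  deltas <- replicate(2000, {
    take <- c(sample(idx_b, n_b, replace = TRUE),
              sample(idx_m, n_m, replace = TRUE))
    la <- labels[take]
    roc_auc(a[take], la, direction = "greater")$auroc -
      roc_auc(b[take], la, direction = "greater")$auroc
  })
  expect_equal(var_delong, stats::var(deltas), tolerance = 0.2)
})

test_that("Youden metrics recover the separating cutoff", {
  labels <- c("benign", "benign", "benign", "malignant", "malignant",
              "malignant")
  y <- youden_metrics(1:6, labels)
  expect_equal(y$cutoff, 3.5)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  expect_equal(y$ppv, 1)
  expect_equal(y$npv, 1)
  expect_equal(y$accuracy, 1)

  flat <- youden_metrics(rep(1, 6), labels)
  expect_equal(flat$sensitivity + flat$specificity, 1)
})

test_that("diagnostic metrics are invariant under monotone score transforms", {
  set.seed(61)
  scores <- rnorm(30)
  labels <- rep(c("benign", "malignant"), 15)
  base <- youden_metrics(scores, labels)
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) atan(x) * 10)) {
    tr <- youden_metrics(f(scores), labels)
    cols <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
    expect_equal(tr[, cols], base[, cols])
  }
  r0 <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels)$auroc, r0$auroc)
})

test_that("ICC(2,1) is exact for identical raters and recovers variance ratios", {
  x <- rnorm(20, 5)
  perfect <- icc_agreement(cbind(x, x))
  expect_identical(perfect$icc, 1)

  # no subject variance: agreement should hover around zero
  set.seed(67)
  noise <- cbind(rnorm(100), rnorm(100))
  r0 <- icc_agreement(noise)
  expect_lt(abs(r0$icc), 0.25)
  expect_true(r0$ci_low <= 0.05)

  # known variance components: true ICC = 1 / (1 + sigma_e^2)
  truth <- 1 / (1 + 0.33^2)
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    subj <- rnorm(200, sd = 1)
    ratings <- cbind(subj + rnorm(200, sd = 0.33),
                     subj + rnorm(200, sd = 0.33))
    r <- icc_agreement(ratings)
    expect_gt(truth, r$ci_low)
    expect_lt(truth, r$ci_high)
  }

  expect_error(icc_agreement(cbind(1:3, 1:3)), "5 subjects")
  expect_error(icc_agreement(matrix(1:12, 4, 3)), "2 rater")
  bad <- cbind(c(1:5), c(1, NA, 3, 4, 5))
  expect_error(icc_agreement(bad), "complete")
})

test_that("percentage change follows 100 * (late - early) / early", {
  expect_equal(percent_change(2.0, 2.2), 10)
  expect_equal(percent_change(3, 3), 0)
  expect_equal(percent_change(1.06, 0.81), 100 * (0.81 - 1.06) / 1.06)
  expect_true(is.na(percent_change(0, 1)))
  expect_true(is.na(percent_change(NA, 1)))
})
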