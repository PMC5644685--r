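test_that("lesion masks are reproducible and match analytic sphere volume", {
  spec <- phantom_spec(grid_shape = c(40, 40, 40), spacing = c(1, 1, 1),
                       lesion_radius_mm = c(10, 10), seed = 5)
  set.seed(5)
  m1 <- make_lesion_mask(spec)
  set.seed(5)
  m2 <- make_lesion_mask(spec)
  expect_identical(m1$flags, m2$flags)

  # all semi-axes 10 mm: a sphere of volume 4/3 pi 10^3 = 4188.8 voxels
  expect_lt(abs(sum(m1$flags) - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.05)
})

test_that("lesions stay inside the grid across seeds", {
  spec <- phantom_spec(seed = 1)
  for (s in 1:30) {
    set.seed(s)
    m <- make_lesion_mask(spec)
    flags <- m$flags
    expect_gt(sum(flags), 0)
    # no lesion voxel on any face of the grid
    expect_false(any(flags[1, , ]) || any(flags[dim(flags)[1], , ]) ||
                   any(flags[, 1, ]) || any(flags[, dim(flags)[2], ]) ||
                   any(flags[, , 1]) || any(flags[, , dim(flags)[3]]))
  }
})

test_that("noiseless homogeneous lesions equal the class mean exactly", {
  spec <- phantom_spec(het_sd_benign = 0, het_sd_malignant = 0,
                       noise_sd = 0, seed = 9)
  case <- make_case(spec, "malignant", "P001", case_seed = 9)
  inside <- case$early$values[case$mask$flags]
  expect_true(all(inside == spec$malignant_mean_suv))
  outside <- case$early$values[!case$mask$flags]
  expect_true(all(outside == spec$background_suv))
  # late volume scales the signal by the retention slope
  expect_equal(unique(case$late$values[case$mask$flags]),
               spec$malignant_mean_suv * 1.10)
})

test_that("lesion voxel SD combines texture and noise variances", {
  spec <- phantom_spec(grid_shape = c(50, 50, 50), spacing = c(2, 2, 2),
                       lesion_radius_mm = c(20, 20), seed = 13)
  case <- make_case(spec, "malignant", "P001", case_seed = 13)
  inside <- case$early$values[case$mask$flags]
  expect_gt(length(inside), 3000)
  expected_sd <- sqrt(spec$het_sd_malignant^2 + spec$noise_sd^2)
  expect_lt(abs(sd(inside) - expected_sd) / expected_sd, 0.1)
})

test_that("cases are reproducible by seed and distinct across patients", {
  spec <- phantom_spec(seed = 17)
  a <- make_case(spec, "benign", "P001", case_seed = 1234)
  b <- make_case(spec, "benign", "P001", case_seed = 1234)
  expect_identical(a$early$values, b$early$values)
  expect_identical(a$mask$flags, b$mask$flags)
  c2 <- make_case(spec, "benign", "P002", case_seed = 5678)
  expect_false(identical(a$early$values, c2$early$values))
})

test_that("generated uptake values are non-negative everywhere", {
  spec <- phantom_spec(noise_sd = 2, background_suv = 0.1, seed = 19)
  case <- make_case(spec, "benign", "P001", case_seed = 19)
  expect_gte(min(case$early$values), 0)
  expect_gte(min(case$late$values), 0)
})

test_that("cohort simulation writes a complete, reproducible bundle", {
  spec <- phantom_spec(n_benign = 2, n_malignant = 2,
                       grid_shape = c(24, 24, 24),
                       lesion_radius_mm = c(10, 14), seed = 23)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- make_cohort(spec, dir1)
  m2 <- make_cohort(spec, dir2)

  expect_equal(nrow(m1), 8)  # 4 cases x 2 timepoints
  expect_setequal(unique(m1$label), c("benign", "malignant"))
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  expect_true(file.exists(file.path(dir1, "ground_truth.json")))
  expect_true(all(file.exists(file.path(dir1, m1$volume_path))))

  # same seed, different directory: identical manifest and volume bytes
  expect_identical(readLines(file.path(dir1, "manifest.csv")),
                   readLines(file.path(dir2, "manifest.csv")))
  v1 <- file.path(dir1, m1$volume_path[1])
  v2 <- file.path(dir2, m2$volume_path[1])
  expect_identical(unname(tools::md5sum(v1)), unname(tools::md5sum(v2)))
})

test_that("a single-class cohort is generated but refused downstream", {
  spec <- phantom_spec(n_benign = 0, n_malignant = 3,
                       grid_shape = c(24, 24, 24),
                       lesion_radius_mm = c(10, 14), seed = 29)
  dir <- withr::local_tempdir()
  manifest <- make_cohort(spec, dir)
  expect_true(all(manifest$label == "malignant"))
  features <- cohort_features(read_manifest(file.path(dir, "manifest.csv")))
  expect_error(summarize_cohort(features), "both benign and malignant")
})

test_that("identical generating parameters drive the SUVmax AUROC to chance", {
  spec <- phantom_spec(n_benign = 10, n_malignant = 10,
                       malignant_mean_suv = 2.3, het_sd_malignant = 0.1,
                       retention_malignant = -0.15,
                       grid_shape = c(24, 24, 24),
                       lesion_radius_mm = c(10, 16), seed = 31)
  labels <- c(rep("benign", 10), rep("malignant", 10))
  suvmax <- vapply(seq_along(labels), function(i) {
    case <- make_case(spec, labels[i], sprintf("P%03d", i),
                      case_seed = 1000 + i)
    max(case$early$values[case$mask$flags])
  }, numeric(1))
  r <- roc_auc(suvmax, labels, direction = "greater")
  expect_gte(0.5, r$ci_low)
  expect_lte(0.5, r$ci_high)
})
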