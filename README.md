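# petrad

Intratumoural heterogeneity analysis of ^18F-FDG PET tumour volumes, built
for the benign-versus-malignant discrimination problem in
neurofibromatosis-1: distinguishing symptomatic benign neurofibromas from
malignant peripheral nerve sheath tumours (MPNSTs) using texture-based
heterogeneity parameters alongside standard SUV metrics, at two acquisition
timepoints (~1.5 h and ~4 h post-injection).

The package provides, as a tidyverse-style pipeline (data frames in,
tibbles out):

- **Volume model** — NIfTI volume and VOI-mask I/O, body-weight SUV
  normalisation (`SUV = C[Bq/ml] * w[g] / D[Bq]`), VOI extraction.
- **Texture features** — 64-level fixed-bin-number min–max quantisation of
  the VOI, then 15 per-lesion parameters: SUVmax, SUVmean, SUVpeak (1 ml
  spherical local mean); first-order SD, entropy
  (−Σ hₗ log₂ hₗ), uniformity (Σ hₗ²); the four grey-level co-occurrence
  matrix (GLCM, 3D, 13 directions, merged symmetric matrix) features
  contrast Σ(i−j)²pᵢⱼ, entropy, uniformity, homogeneity Σpᵢⱼ/(1+(i−j)²);
  the four Amadasun–King neighbourhood grey-tone difference matrix (NGTDM,
  26-neighbour, complete-neighbourhood rule) features coarseness,
  contrast, busyness, complexity; and the combined ratio
  SUVmax / NGTDM contrast.
- **Cohort statistics** — Mann–Whitney group tests, Spearman correlation
  versus SUVmax, empirical AUROC with DeLong variance/CI and paired DeLong
  comparison against SUVmax, diagnostic metrics (sensitivity, specificity,
  PPV, NPV, accuracy) at the Youden-optimal cutoff, two-way
  random-effects absolute-agreement ICC(2,1) for inter-observer data, and
  early→late percentage change `100·(late−early)/early`.
- **Synthetic phantom cohort** — a seeded generator of two-class,
  two-timepoint ellipsoidal lesion phantoms (default 30 benign / 24
  malignant) with class-specific uptake, heterogeneity and retention, used
  to validate the full pipeline.

## Worked example

Simulate the default phantom cohort, extract all features at both
timepoints and run the full analysis:

```r
library(petrad)
library(dplyr)

spec <- phantom_spec(seed = 11)
spec
#> <phantom_spec> 30 benign + 24 malignant, grid 32x32x40 @ (4.7, 4.7, 3.27) mm, seed 11
#>   mean SUV 2.30 / 7.00, texture SD 0.10 / 1.30, noise SD 0.25

summary <- run_pipeline(spec, "phantom-run")
summary
#> <cohort_summary>
#>   group_comparison: 45 rows; roc: 45 rows; spearman: 28 rows
#>   best early-timepoint discriminators (AUROC):
#>     suv_max                      1.000
#>     suv_mean                     1.000
#>     suv_peak                     1.000

tidy(summary) |>
  filter(timepoint == "early",
         feature %in% c("suv_max", "sd", "fo_entropy", "ngtdm_coarseness")) |>
  select(feature, auroc, ci_low, ci_high, p_vs_suvmax, sensitivity, specificity)
#>            feature auroc ci_low ci_high p_vs_suvmax sensitivity specificity
#> 1          suv_max 1.000  1.000   1.000          NA       1.000       1.000
#> 2               sd 1.000  1.000   1.000    1.00e+00       1.000       1.000
#> 3       fo_entropy 0.997  0.991   1.000    4.12e-01       0.958       1.000
#> 4 ngtdm_coarseness 0.589  0.435   0.743    1.58e-07       0.792       0.433
```

Reading the table: on this phantom cohort the SUV parameters and the
first-order heterogeneity parameters separate the classes essentially
perfectly (AUROC ≈ 1, p < 0.01 on the Mann–Whitney test in
`summary$group_comparison`), first-order entropy is higher and uniformity
lower in malignant lesions, and the paired DeLong test shows no parameter
outperforming SUVmax — the qualitative structure expected of a cohort in
which malignant lesions have both higher and more heterogeneous uptake.
`run_pipeline()` also writes `features.csv` and a `report/` directory
(CSV tables plus a full-precision `report.json`) under the output
directory; reruns with the same spec are byte-identical.

The statistical layer works on any feature table with `patient_id`,
`label`, `timepoint` and feature columns — clinical cohorts enter through
a manifest CSV (`read_manifest()` / `cohort_features()`) pointing at
NIfTI volumes and masks:

```r
r <- roc_auc(c(1.8, 2.2, 2.9, 3.4, 6.1, 7.4, 8.0),
             c("benign", "benign", "benign", "benign",
               "malignant", "malignant", "malignant"))
r
#> <pet_roc> AUROC 1.000 (95% CI 1.000-1.000), greater_is_malignant, n = 4 benign / 3 malignant
autoplot(r)   # ggplot ROC curve
```

A thin command-line front end over the same functions is installed at
`inst/cli/petrad.R` (subcommands `simulate`, `extract`, `analyse`, `all`).

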