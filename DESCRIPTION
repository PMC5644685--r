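Package: petrad
Title: Intratumoural Heterogeneity Analysis of FDG PET Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Texture-based heterogeneity analysis of 18F-FDG PET tumour
    volumes of interest: 64-level intensity quantisation; first-order,
    grey-level co-occurrence matrix (GLCM) and neighbourhood grey-tone
    difference matrix (NGTDM) features; SUV metrics including a 1 ml
    SUVpeak; benign-versus-malignant cohort statistics (Mann-Whitney
    tests, AUROC with DeLong confidence intervals and paired AUROC
    comparisons, Youden-optimal diagnostic metrics, intraclass
    correlation, dual-timepoint percentage change); and a seeded
    two-class, two-timepoint lesion phantom generator for validation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
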