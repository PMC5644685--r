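#' Read a cohort manifest CSV
#'
#' The manifest maps each patient and timepoint to its volume and mask
#' files: columns `patient_id`, `label` (benign/malignant), `timepoint`
#' (early/late), `volume_path`, `mask_path`, `units` (SUV/BQML) and,
#' for BQML volumes, `dose_mbq`, `weight_kg`, `uptake_min`. Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return A tibble with absolute `volume_path` / `mask_path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("manifest not found: ", path, call. = FALSE)
  }
  m <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("patient_id", "label", "timepoint", "volume_path",
                "mask_path", "units")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    stop("manifest is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  dplyr::mutate(m,
                volume_path = resolve(.data$volume_path),
                mask_path = resolve(.data$mask_path))
}

#' Extract heterogeneity features for a whole cohort
#'
#' Runs [extract_features()] for every manifest row (one lesion per
#' patient per timepoint), converting BQML volumes to SUV first. A case
#' whose files cannot be read or whose mask does not match its volume is
#' skipped with a warning and recorded in the `failures` attribute of
#' the result; the run continues.
#'
#' @param manifest a manifest tibble (see [read_manifest()]) or a path
#'   to a manifest CSV.
#' @param n_bins,peak_volume_ml,ngtdm_epsilon passed to
#'   [extract_features()].
#' @return A tibble with `patient_id`, `label`, `timepoint`, the 15
#'   feature columns, `n_voxels` and `voi_ml`.
#' @export
cohort_features <- function(manifest, n_bins = 64L, peak_volume_ml = 1.0,
                            ngtdm_epsilon = 1e-6) {
  if (is.character(manifest)) {
    manifest <- read_manifest(manifest)
  }
  failures <- character(0)
  rows <- purrr::pmap(manifest, function(patient_id, label, timepoint,
                                         volume_path, mask_path, units,
                                         ...) {
    extra <- list(...)
    tryCatch({
      vol <- load_volume(volume_path, units = units)
      if (vol$units == "BQML") {
        meta <- acquisition_meta(extra$dose_mbq, extra$weight_kg,
                                 extra$uptake_min,
                                 timepoint = timepoint)
        vol <- to_suv(vol, meta)
      }
      mask <- load_mask(mask_path, vol)
      fv <- extract_features(vol, mask, n_bins = n_bins,
                             peak_volume_ml = peak_volume_ml,
                             ngtdm_epsilon = ngtdm_epsilon)
      dplyr::bind_cols(
        tibble::tibble(patient_id = patient_id, label = label,
                       timepoint = timepoint),
        fv
      )
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("%s/%s: %s", patient_id, timepoint,
                             conditionMessage(e)))
      NULL
    })
  })
  out <- dplyr::bind_rows(rows)
  if (length(failures) > 0) {
    warning(length(failures), " case(s) skipped:\n  ",
            paste(failures, collapse = "\n  "), call. = FALSE)
  }
  attr(out, "failures") <- failures
  out
}

# Long format of the feature columns present in a feature table.
features_long <- function(features) {
  cols <- intersect(feature_names(), names(features))
  tidyr::pivot_longer(
    features[, c("patient_id", "label", "timepoint", cols)],
    dplyr::all_of(cols),
    names_to = "feature", values_to = "value"
  ) |>
    dplyr::mutate(feature = factor(.data$feature, levels = feature_names()))
}

fmt_range <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_character_)
  sprintf("%.3g-%.3g", min(x), max(x))
}

#' Benign-versus-malignant cohort statistics
#'
#' The full statistical analysis of a two-class, two-timepoint feature
#' table, mirroring the structure of the clinical heterogeneity
#' analysis:
#' \itemize{
#'   \item `group_comparison` — per feature and timepoint: median and
#'     range by class, and the Mann-Whitney two-sided p value; plus one
#'     row per feature for the early-to-late percentage change
#'     (pooled median/range, classes compared by Mann-Whitney).
#'   \item `roc` — per feature at each timepoint and for the percentage
#'     change: AUROC with DeLong 95% CI, paired DeLong p versus SUVmax
#'     at the same timepoint (NA for SUVmax itself and for the change
#'     rows), and Youden-optimal cutoff diagnostics (sensitivity,
#'     specificity, PPV, NPV, accuracy).
#'   \item `spearman` — per feature and timepoint: Spearman rho and p
#'     versus SUVmax.
#' }
#' Tests are two-sided throughout with no multiple-testing correction;
#' missing feature values are excluded pairwise per statistic.
#'
#' @param features a feature tibble from [cohort_features()]; must
#'   contain both classes with at least 2 patients each.
#' @param icc_form ICC form recorded in the configuration (used by
#'   reports that add inter-observer data).
#' @return An object of class `cohort_summary`: list of the three
#'   tibbles plus a `config` list naming every method used.
#' @export
summarize_cohort <- function(features, icc_form = "agreement") {
  stopifnot(is.data.frame(features))
  labs <- unique(features$label)
  if (!all(c("benign", "malignant") %in% labs)) {
    stop("cohort must contain both benign and malignant cases",
         call. = FALSE)
  }
  n_per <- features |>
    dplyr::distinct(.data$patient_id, .data$label) |>
    dplyr::count(.data$label)
  if (any(n_per$n < 2)) {
    stop("need at least 2 patients per class for group comparisons",
         call. = FALSE)
  }

  long <- features_long(features)

  group_tp <- long |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$feature, .data$timepoint) |>
    dplyr::group_modify(function(d, key) {
      b <- d$value[d$label == "benign"]
      m <- d$value[d$label == "malignant"]
      mw <- mann_whitney(b, m)
      tibble::tibble(
        median_benign = stats::median(b), range_benign = fmt_range(b),
        median_malignant = stats::median(m), range_malignant = fmt_range(m),
        p_value = mw$p_value, n_benign = length(b), n_malignant = length(m)
      )
    }) |>
    dplyr::ungroup()

  # per-patient early -> late percentage change of every feature
  change <- long |>
    tidyr::pivot_wider(names_from = "timepoint",
                       values_from = "value") |>
    dplyr::mutate(value = percent_change(.data$early, .data$late)) |>
    dplyr::select("patient_id", "label", "feature", "value") |>
    dplyr::mutate(timepoint = "pct_change")

  group_change <- change |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(d, key) {
      b <- d$value[d$label == "benign"]
      m <- d$value[d$label == "malignant"]
      mw <- mann_whitney(b, m)
      tibble::tibble(
        timepoint = "pct_change",
        median_pooled = stats::median(d$value),
        range_pooled = fmt_range(d$value),
        p_value = mw$p_value, n_benign = length(b), n_malignant = length(m)
      )
    }) |>
    dplyr::ungroup()

  roc_input <- dplyr::bind_rows(
    long |> dplyr::select("patient_id", "label", "feature",
                          "timepoint", "value"),
    change
  )

  suvmax_by_tp <- roc_input |>
    dplyr::filter(.data$feature == "suv_max",
                  .data$timepoint %in% c("early", "late"))

  roc_tbl <- roc_input |>
    dplyr::group_by(.data$feature, .data$timepoint) |>
    dplyr::group_modify(function(d, key) {
      d <- d[is.finite(d$value), ]
      if (length(unique(d$label)) < 2 || nrow(d) < 4) {
        return(tibble::tibble(auroc = NA_real_))
      }
      r <- roc_auc(d$value, d$label)
      y <- youden_metrics(d$value, d$label)
      p_vs <- NA_real_
      if (key$timepoint %in% c("early", "late") &&
          key$feature != "suv_max") {
        ref <- suvmax_by_tp[suvmax_by_tp$timepoint == key$timepoint, ]
        paired <- dplyr::inner_join(
          d, ref[, c("patient_id", "value")],
          by = "patient_id", suffix = c("", "_suvmax"))
        p_vs <- delong_compare(paired$value, paired$value_suvmax,
                               paired$label)$p_value
      }
      dplyr::bind_cols(
        tidy.pet_roc(r)[, c("auroc", "ci_low", "ci_high", "direction")],
        tibble::tibble(p_vs_suvmax = p_vs),
        y[, c("cutoff", "sensitivity", "specificity", "ppv", "npv",
              "accuracy")]
      )
    }) |>
    dplyr::ungroup()

  spearman_tbl <- long |>
    dplyr::filter(.data$feature != "suv_max") |>
    dplyr::group_by(.data$feature, .data$timepoint) |>
    dplyr::group_modify(function(d, key) {
      ref <- long[long$feature == "suv_max" &
                    long$timepoint == key$timepoint, ]
      paired <- dplyr::inner_join(
        d, ref[, c("patient_id", "value")],
        by = "patient_id", suffix = c("", "_suvmax"))
      ok <- is.finite(paired$value) & is.finite(paired$value_suvmax)
      if (sum(ok) < 3) return(tibble::tibble(rho = NA_real_))
      spearman_cor(paired$value[ok], paired$value_suvmax[ok])
    }) |>
    dplyr::ungroup()

  structure(
    list(
      group_comparison = dplyr::bind_rows(group_tp, group_change),
      roc = roc_tbl,
      spearman = spearman_tbl,
      config = list(
        group_test = "mann_whitney_two_sided",
        auroc = "empirical_delong_ci",
        auroc_comparison = "delong_paired",
        cutoff_rule = "youden_max_spec_tiebreak",
        correlation = "spearman_t_approx",
        icc_form = icc_form,
        pct_change = "100*(late-early)/early",
        alpha = 0.05,
        multiple_testing_correction = "none"
      )
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  group_comparison: %d rows; roc: %d rows; spearman: %d rows\n",
              nrow(x$group_comparison), nrow(x$roc), nrow(x$spearman)))
  top <- x$roc |>
    dplyr::filter(.data$timepoint == "early") |>
    dplyr::arrange(dplyr::desc(.data$auroc)) |>
    utils::head(3)
  cat("  best early-timepoint discriminators (AUROC):\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-28s %.3f\n", as.character(top$feature[i]),
                top$auroc[i]))
  }
  invisible(x)
}

#' @export
tidy.cohort_summary <- function(x, ...) {
  x$roc
}

#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    n_features = length(unique(x$group_comparison$feature)),
    n_tests = nrow(x$group_comparison),
    alpha = x$config$alpha
  )
}

# Round numeric columns to a number of significant figures for CSV
# serialisation; full precision goes to the JSON mirror.
signif_df <- function(df, digits) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  ~ signif(.x, digits)))
}

#' Write report files for a cohort summary
#'
#' Writes CSV mirrors of the three report tables (values rounded to
#' `digits` significant figures) and a single JSON report holding the
#' same tables at full precision plus the method configuration and
#' package version. Output is deterministic: rerunning on the same
#' summary produces byte-identical files.
#'
#' @param summary a `cohort_summary`.
#' @param dir output directory, created if absent.
#' @param digits significant figures for the CSV serialisation.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(summary, dir, digits = 4) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("group_comparison", "roc", "spearman")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(signif_df(summary[[nm]], digits), p, na = "")
    paths <- c(paths, p)
  }
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(
      tables = list(
        group_comparison = summary$group_comparison,
        roc = summary$roc,
        spearman = summary$spearman
      ),
      config = summary$config,
      package_version = as.character(utils::packageVersion("petrad"))
    ),
    jp, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(paths, jp))
}

#' Run the full phantom-to-report pipeline
#'
#' Simulates (or ingests) a cohort, extracts features for every case and
#' timepoint, runs the cohort statistics and writes the report files.
#' With a fixed spec/seed the whole run is deterministic.
#'
#' @param spec a [phantom_spec()] to simulate, or a path to an existing
#'   manifest CSV.
#' @param out_dir output directory; receives `cohort/` (when
#'   simulating), `features.csv` and `report/`.
#' @param n_bins,peak_volume_ml,ngtdm_epsilon feature settings.
#' @return The `cohort_summary`, invisibly, with the feature table in
#'   attribute `features`.
#' @export
run_pipeline <- function(spec, out_dir, n_bins = 64L, peak_volume_ml = 1.0,
                         ngtdm_epsilon = 1e-6) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(spec, "phantom_spec")) {
    manifest <- make_cohort(spec, file.path(out_dir, "cohort"))
    manifest <- read_manifest(attr(manifest, "manifest_path"))
  } else {
    manifest <- read_manifest(spec)
  }
  features <- cohort_features(manifest, n_bins = n_bins,
                              peak_volume_ml = peak_volume_ml,
                              ngtdm_epsilon = ngtdm_epsilon)
  readr::write_csv(signif_df(features, 10), file.path(out_dir, "features.csv"),
                   na = "")
  summary <- summarize_cohort(features)
  write_report(summary, file.path(out_dir, "report"))
  attr(summary, "features") <- features
  invisible(summary)
}
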