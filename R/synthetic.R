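#' Specification of a synthetic two-class lesion phantom cohort
#'
#' Defines the generating conditions for a benign/malignant,
#' early/late-timepoint phantom cohort. The defaults emulate the
#' clinical structure the analysis targets: 30 benign and 24 malignant
#' lesions; benign lesions with low, spatially homogeneous uptake
#' (mean SUV 2.3) and malignant lesions with high, spatially
#' heterogeneous uptake (mean SUV 7.0); two timepoints at about 1.5 h
#' and 4 h with benign washout (-15%) and malignant retention (+10%);
#' PET-like voxel geometry (4.7 x 4.7 x 3.27 mm).
#'
#' Lesion texture is a spatially structured heterogeneity field scaled
#' to the class heterogeneity SD, plus independent voxelwise measurement
#' noise. The field mixes (default weights 0.85 / 0.15) a
#' centre-to-rim radial gradient — the necrotic-core /
#' hypermetabolic-rim pattern of aggressive lesions, which spreads the
#' voxel histogram across its range — with a spatially correlated
#' Gaussian component (smoothed white noise, correlation length 6 mm,
#' about the PET spatial resolution). Benign texture SD (0.1) sits well
#' below the measurement noise (0.25), malignant texture SD (1.3) well
#' above it, so total voxelwise SD is about 0.27 vs 1.32 for the two
#' classes while the *spatial and histogram* character differs: benign
#' variation is essentially uncorrelated image noise with a tight
#' unimodal histogram, malignant variation is organised structure with
#' a broad histogram.
#'
#' @param n_benign,n_malignant class sizes.
#' @param grid_shape voxels per axis.
#' @param spacing voxel size in mm.
#' @param benign_mean_suv,malignant_mean_suv class mean lesion SUV.
#' @param het_sd_benign,het_sd_malignant SD (SUV) of the correlated
#'   texture field per class.
#' @param texture_correlation_mm Gaussian smoothing length (sigma, mm)
#'   of the correlated component of the texture field.
#' @param rim_gradient_weight mixing weight in `[0, 1]` of the
#'   centre-to-rim gradient component (the remainder goes to the
#'   correlated Gaussian component).
#' @param noise_sd SD (SUV) of independent voxelwise noise, applied to
#'   the whole volume at both timepoints.
#' @param retention_benign,retention_malignant fractional change of the
#'   noise-free signal from early to late (-0.15 = 15% washout).
#' @param background_suv mean background uptake outside the lesion.
#' @param lesion_radius_mm range (min, max) of ellipsoid semi-axes.
#' @param seed root seed; per-case substreams are derived from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_benign = 30L, n_malignant = 24L,
                         grid_shape = c(32L, 32L, 40L),
                         spacing = c(4.7, 4.7, 3.27),
                         benign_mean_suv = 2.3, malignant_mean_suv = 7.0,
                         het_sd_benign = 0.1, het_sd_malignant = 1.3,
                         texture_correlation_mm = 6,
                         rim_gradient_weight = 0.85,
                         noise_sd = 0.25,
                         retention_benign = -0.15,
                         retention_malignant = 0.10,
                         background_suv = 0.5,
                         lesion_radius_mm = c(14, 26),
                         seed = 42L) {
  spec <- list(
    n_benign = as.integer(n_benign), n_malignant = as.integer(n_malignant),
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    benign_mean_suv = benign_mean_suv,
    malignant_mean_suv = malignant_mean_suv,
    het_sd_benign = het_sd_benign, het_sd_malignant = het_sd_malignant,
    texture_correlation_mm = texture_correlation_mm,
    rim_gradient_weight = rim_gradient_weight,
    noise_sd = noise_sd,
    retention_benign = retention_benign,
    retention_malignant = retention_malignant,
    background_suv = background_suv,
    lesion_radius_mm = as.numeric(lesion_radius_mm),
    seed = as.integer(seed),
    rng_kind = "Mersenne-Twister"
  )
  if (spec$n_benign < 0 || spec$n_malignant < 0) {
    stop("class counts must be >= 0", call. = FALSE)
  }
  if (spec$benign_mean_suv <= 0 || spec$malignant_mean_suv <= 0) {
    stop("class mean SUVs must be > 0", call. = FALSE)
  }
  if (spec$het_sd_benign < 0 || spec$het_sd_malignant < 0 ||
      spec$noise_sd < 0) {
    stop("SD parameters must be >= 0", call. = FALSE)
  }
  if (spec$rim_gradient_weight < 0 || spec$rim_gradient_weight > 1) {
    stop("`rim_gradient_weight` must be in [0, 1]", call. = FALSE)
  }
  if (length(spec$lesion_radius_mm) != 2L ||
      spec$lesion_radius_mm[1] > spec$lesion_radius_mm[2] ||
      spec$lesion_radius_mm[1] <= 0) {
    stop("`lesion_radius_mm` must be an increasing positive range",
         call. = FALSE)
  }
  extent <- spec$grid_shape * spec$spacing
  if (any(2 * (spec$lesion_radius_mm[2] + spec$spacing) >= extent)) {
    stop("largest lesion radius does not fit inside the grid with margin",
         call. = FALSE)
  }
  structure(spec, class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d benign + %d malignant, grid %s @ (%s) mm, seed %d\n",
              x$n_benign, x$n_malignant,
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "), x$seed))
  cat(sprintf("  mean SUV %.2f / %.2f, texture SD %.2f / %.2f, noise SD %.2f\n",
              x$benign_mean_suv, x$malignant_mean_suv,
              x$het_sd_benign, x$het_sd_malignant, x$noise_sd))
  invisible(x)
}

# Derived per-case seed, kept inside 32-bit integer range.
case_seed <- function(root_seed, case_index) {
  as.integer((as.numeric(root_seed) * 7919 + case_index * 104729) %%
               2147483647)
}

#' Rasterise a random ellipsoidal lesion mask
#'
#' Draws ellipsoid semi-axes uniformly from the spec's radius range and
#' a centre uniformly positioned so the ellipsoid fits inside the grid
#' with a one-voxel margin, then rasterises by voxel-centre membership.
#' Uses (and advances) the current RNG state; call `set.seed()` first
#' for reproducibility.
#'
#' @param spec a [phantom_spec()].
#' @return A `pet_mask`, with attributes `semi_axes_mm` and `centre_mm`.
#' @export
make_lesion_mask <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  semi <- stats::runif(3, spec$lesion_radius_mm[1], spec$lesion_radius_mm[2])
  extent <- spec$grid_shape * spec$spacing
  margin <- semi + spec$spacing
  if (any(extent - 2 * margin <= 0)) {
    stop("lesion does not fit inside the grid", call. = FALSE)
  }
  centre <- stats::runif(3, margin, extent - margin)
  ax <- (seq_len(spec$grid_shape[1]) - 0.5) * spec$spacing[1]
  ay <- (seq_len(spec$grid_shape[2]) - 0.5) * spec$spacing[2]
  az <- (seq_len(spec$grid_shape[3]) - 0.5) * spec$spacing[3]
  dx2 <- ((ax - centre[1]) / semi[1])^2
  dy2 <- ((ay - centre[2]) / semi[2])^2
  dz2 <- ((az - centre[3]) / semi[3])^2
  flags <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  if (!any(flags)) {
    stop("rasterised lesion mask is empty", call. = FALSE)
  }
  m <- voi_mask(flags)
  attr(m, "semi_axes_mm") <- semi
  attr(m, "centre_mm") <- centre
  m
}

# Heterogeneity field over the grid: weighted mix of a centre-to-rim
# radial gradient (normalised ellipsoidal radius raised to a random
# exponent, random core offset; uniform-ish histogram over the lesion)
# and a correlated Gaussian field (smoothed white noise). Standardised
# to mean 0, SD 1 over the lesion voxels. Uses the current RNG state.
heterogeneity_field <- function(spec, mask) {
  dims <- spec$grid_shape
  w <- spec$rim_gradient_weight

  smooth_part <- array(0, dims)
  if (w < 1) {
    white <- array(stats::rnorm(prod(dims)), dims)
    sm <- gaussian_smooth_3d(white, spec$texture_correlation_mm / spec$spacing)
    s <- stats::sd(sm[mask$flags])
    if (s > 0) smooth_part <- sm / s
  }

  radial_part <- array(0, dims)
  if (w > 0) {
    semi <- attr(mask, "semi_axes_mm")
    centre <- attr(mask, "centre_mm")
    core <- centre + stats::runif(3, -0.2, 0.2) * semi
    expo <- stats::runif(1, 2.2, 3.8)
    ax <- (seq_len(dims[1]) - 0.5) * spec$spacing[1]
    ay <- (seq_len(dims[2]) - 0.5) * spec$spacing[2]
    az <- (seq_len(dims[3]) - 0.5) * spec$spacing[3]
    rho2 <- outer(outer(((ax - core[1]) / semi[1])^2,
                        ((ay - core[2]) / semi[2])^2, `+`),
                  ((az - core[3]) / semi[3])^2, `+`)
    rad <- pmin(sqrt(rho2), 1)^expo
    s <- stats::sd(rad[mask$flags])
    if (s > 0) radial_part <- rad / s
  }

  f <- w * radial_part + (1 - w) * smooth_part
  inside <- f[mask$flags]
  s_tot <- sqrt(mean((inside - mean(inside))^2))
  if (s_tot == 0) return(array(0, dims))
  (f - mean(inside)) / s_tot
}

#' Simulate one two-timepoint phantom case
#'
#' Early volume: background plus, inside the lesion mask, the class mean
#' plus the structured heterogeneity field (centre-to-rim gradient mixed
#' with a correlated Gaussian field, standardised and scaled to the
#' class heterogeneity SD — see [phantom_spec()]), plus independent
#' voxelwise Gaussian noise everywhere. Late volume: the noise-free
#' early signal scaled by (1 + class retention slope), with fresh noise.
#' Values are clipped at 0 (physical non-negativity; a slight truncation
#' of the noise distribution).
#'
#' @param spec a [phantom_spec()].
#' @param label `"benign"` or `"malignant"`.
#' @param patient_id identifier string.
#' @param case_seed integer seed for this case's RNG substream; the
#'   global RNG is seeded with it.
#' @return An object of class `phantom_case`: list with `patient_id`,
#'   `label`, `early`/`late` (`pet_volume`s in SUV), `mask`
#'   (`pet_mask`), `ground_truth` (generating parameters).
#' @export
make_case <- function(spec, label = c("benign", "malignant"),
                      patient_id = "P001", case_seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  label <- match.arg(label)
  set.seed(case_seed)
  mask <- make_lesion_mask(spec)
  dims <- spec$grid_shape
  mean_suv <- if (label == "benign") spec$benign_mean_suv else
    spec$malignant_mean_suv
  het_sd <- if (label == "benign") spec$het_sd_benign else
    spec$het_sd_malignant
  slope <- if (label == "benign") spec$retention_benign else
    spec$retention_malignant

  field <- array(0, dims)
  if (het_sd > 0) {
    field <- het_sd * heterogeneity_field(spec, mask)
  }

  signal <- array(spec$background_suv, dims)
  signal[mask$flags] <- mean_suv + field[mask$flags]

  noise_early <- array(stats::rnorm(prod(dims), sd = spec$noise_sd), dims)
  noise_late <- array(stats::rnorm(prod(dims), sd = spec$noise_sd), dims)
  early <- pmax(signal + noise_early, 0)
  late <- pmax(signal * (1 + slope) + noise_late, 0)

  structure(
    list(
      patient_id = patient_id,
      label = label,
      early = image_volume(early, spec$spacing, "SUV"),
      late = image_volume(late, spec$spacing, "SUV"),
      mask = mask,
      ground_truth = list(
        mean_suv = mean_suv, het_sd = het_sd, noise_sd = spec$noise_sd,
        retention_slope = slope, case_seed = case_seed,
        semi_axes_mm = attr(mask, "semi_axes_mm"),
        centre_mm = attr(mask, "centre_mm"),
        n_lesion_voxels = sum(mask$flags)
      )
    ),
    class = "phantom_case"
  )
}

#' Simulate a phantom cohort and write it to disk
#'
#' Generates `n_benign + n_malignant` two-timepoint cases with
#' independent per-case RNG substreams derived from the root seed, and
#' writes NIfTI volumes and masks, a cohort manifest CSV (the input
#' schema of [cohort_features()]) and a `ground_truth.json` manifest of
#' the generating parameters. Re-running with the same spec reproduces
#' the cohort exactly.
#'
#' @param spec a [phantom_spec()].
#' @param dir output directory; created if absent.
#' @return The manifest tibble (columns `patient_id`, `label`,
#'   `timepoint`, `volume_path`, `mask_path`, `units`, `dose_mbq`,
#'   `weight_kg`, `uptake_min`), invisibly, with the manifest path in
#'   attribute `manifest_path`.
#' @export
make_cohort <- function(spec, dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_benign + spec$n_malignant < 2L) {
    stop("need at least 2 cases in total", call. = FALSE)
  }
  vol_dir <- file.path(dir, "volumes")
  dir.create(vol_dir, recursive = TRUE, showWarnings = FALSE)
  labels <- c(rep("benign", spec$n_benign),
              rep("malignant", spec$n_malignant))
  rows <- list()
  truth <- list()
  for (i in seq_along(labels)) {
    pid <- sprintf("P%03d", i)
    cs <- case_seed(spec$seed, i)
    case <- make_case(spec, labels[i], pid, cs)
    mask_path <- file.path(vol_dir, paste0(pid, "_mask.nii"))
    mask_img <- image_volume(array(as.numeric(case$mask$flags),
                                   dim = dim(case$mask$flags)),
                             spec$spacing, "SUV")
    write_volume(mask_img, mask_path)
    for (tp in c("early", "late")) {
      vol_path <- file.path(vol_dir, paste0(pid, "_", tp, ".nii"))
      write_volume(case[[tp]], vol_path)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid, label = labels[i], timepoint = tp,
        volume_path = file.path("volumes", basename(vol_path)),
        mask_path = file.path("volumes", basename(mask_path)),
        units = "SUV", dose_mbq = 350, weight_kg = 70,
        uptake_min = if (tp == "early") 90 else 250
      )
    }
    truth[[pid]] <- case$ground_truth
  }
  manifest <- dplyr::bind_rows(rows)
  manifest_path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, manifest_path)
  jsonlite::write_json(
    list(spec = unclass(spec), cases = truth),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  attr(manifest, "manifest_path") <- manifest_path
  invisible(manifest)
}
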