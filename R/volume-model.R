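#' Construct a PET image volume
#'
#' A `pet_volume` is a 3D scalar grid of uptake values together with the
#' per-axis voxel size in millimetres and a unit tag. Values are either
#' standardised uptake values (`"SUV"`, body-weight normalised) or raw
#' activity concentrations (`"BQML"`, Bq/ml) awaiting conversion with
#' [to_suv()].
#'
#' Voxel coordinates throughout the package are 0-based integer indices in
#' the storage order of the raster file, axis order (x, y, z).
#'
#' @param values numeric 3D array of voxel values; all finite.
#' @param spacing numeric length-3 vector of voxel sizes in mm; all > 0.
#' @param units `"SUV"` or `"BQML"`.
#' @return An object of class `pet_volume`.
#' @export
image_volume <- function(values, spacing, units = c("SUV", "BQML")) {
  units <- match.arg(units)
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    stop("`values` must be a 3D array, got ", length(dim(values)),
         " dimensions", call. = FALSE)
  }
  if (any(dim(values) < 1L)) {
    stop("`values` must have at least one voxel per axis", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` contains non-finite voxels", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive voxel sizes in mm, got (",
         paste(signif(spacing, 4), collapse = ", "), ")", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, units = units),
    class = "pet_volume"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf("<pet_volume> %s grid, spacing (%s) mm, units %s\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "), x$units))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a VOI mask
#'
#' A `pet_mask` is a binary 3D grid co-registered with (same shape as) a
#' `pet_volume`. Any nonzero voxel is inside the volume of interest, so
#' 0/1 and 0/255 mask dialects behave identically.
#'
#' @param flags logical or numeric 3D array; nonzero/`TRUE` means inside.
#' @param reference optional `pet_volume` whose shape the mask must match.
#' @return An object of class `pet_mask`.
#' @export
voi_mask <- function(flags, reference = NULL) {
  flags <- as.array(flags)
  if (length(dim(flags)) != 3L) {
    stop("mask must be a 3D array", call. = FALSE)
  }
  flags <- array(flags != 0, dim = dim(flags))
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "pet_volume"))
    if (!identical(dim(flags), dim(reference$values))) {
      stop("mask shape (", paste(dim(flags), collapse = "x"),
           ") does not match volume shape (",
           paste(dim(reference$values), collapse = "x"), ")", call. = FALSE)
    }
  }
  structure(list(flags = flags), class = "pet_mask")
}

#' @export
print.pet_mask <- function(x, ...) {
  cat(sprintf("<pet_mask> %s grid, %d voxels inside VOI\n",
              paste(dim(x$flags), collapse = "x"), sum(x$flags)))
  invisible(x)
}

#' Acquisition metadata for SUV conversion
#'
#' @param injected_dose_mbq injected activity in MBq, decay-corrected to
#'   scan time (decay correction is assumed done upstream, as on standard
#'   PET consoles; no decay factor is applied here).
#' @param body_weight_kg patient body weight in kg.
#' @param uptake_min minutes post-injection at acquisition.
#' @param timepoint `"early"` (~1.5 h) or `"late"` (~4 h).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_dose_mbq, body_weight_kg,
                             uptake_min, timepoint = c("early", "late")) {
  timepoint <- match.arg(timepoint)
  if (!is.finite(injected_dose_mbq) || injected_dose_mbq <= 0) {
    stop("`injected_dose_mbq` must be > 0", call. = FALSE)
  }
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0) {
    stop("`body_weight_kg` must be > 0", call. = FALSE)
  }
  if (!is.finite(uptake_min) || uptake_min <= 0) {
    stop("`uptake_min` must be > 0", call. = FALSE)
  }
  structure(
    list(injected_dose_mbq = injected_dose_mbq,
         body_weight_kg = body_weight_kg,
         uptake_min = uptake_min,
         timepoint = timepoint),
    class = "acquisition_meta"
  )
}

#' Read a 3D volume from a NIfTI file
#'
#' Reads a NIfTI-1 raster (`.nii` / `.nii.gz`), taking the voxel spacing
#' from the header. A 4D image whose fourth axis is a singleton is
#' squeezed to 3D; any other dimensionality is rejected.
#'
#' @param path path to the NIfTI file.
#' @param units unit tag to attach, `"SUV"` (default) or `"BQML"`.
#' @return A [image_volume()] object.
#' @export
load_volume <- function(path, units = c("SUV", "BQML")) {
  units <- match.arg(units)
  if (!file.exists(path)) {
    stop("volume file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] == 1L) {
    img <- array(img[, , , 1L], dim = dm[1:3])
    dm <- dim(img)
  }
  if (length(dm) != 3L) {
    stop("expected a 3D volume in ", path, ", got dimensions (",
         paste(dm, collapse = ", "), ")", call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("non-positive voxel spacing (", paste(spacing, collapse = ", "),
         ") in header of ", path, call. = FALSE)
  }
  image_volume(array(as.numeric(img), dim = dm), spacing, units)
}

#' Write a volume to a NIfTI file
#'
#' Stores values at double precision so that a write/load round trip
#' reproduces them exactly.
#'
#' @param volume a `pet_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a VOI mask from a NIfTI file
#'
#' Any nonzero voxel is treated as inside the VOI. The mask grid must
#' match the reference volume's shape exactly; masks drawn on a different
#' grid (e.g. a CT grid) must be resampled upstream.
#'
#' @param path path to the NIfTI mask.
#' @param reference the `pet_volume` the mask belongs to.
#' @return A [voi_mask()] object.
#' @export
load_mask <- function(path, reference) {
  stopifnot(inherits(reference, "pet_volume"))
  if (!file.exists(path)) {
    stop("mask file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) == 4L && dm[4] == 1L) {
    img <- array(img[, , , 1L], dim = dm[1:3])
    dm <- dim(img)
  }
  if (length(dm) != 3L) {
    stop("expected a 3D mask in ", path, call. = FALSE)
  }
  mask <- voi_mask(array(as.numeric(img), dim = dm), reference)
  if (!any(mask$flags)) {
    stop("mask ", path, " contains no nonzero voxel", call. = FALSE)
  }
  mask
}

#' Convert an activity-concentration volume to SUV
#'
#' Body-weight SUV: `SUV = concentration [Bq/ml] * body weight [g] /
#' injected dose [Bq]`. Volumes already in SUV pass through unchanged.
#'
#' @param volume a `pet_volume` in `"BQML"` (or `"SUV"`, returned as-is).
#' @param meta an [acquisition_meta()] object.
#' @return A `pet_volume` in SUV units.
#' @export
to_suv <- function(volume, meta) {
  stopifnot(inherits(volume, "pet_volume"))
  if (volume$units == "SUV") {
    return(volume)
  }
  stopifnot(inherits(meta, "acquisition_meta"))
  scale <- (meta$body_weight_kg * 1000) / (meta$injected_dose_mbq * 1e6)
  image_volume(volume$values * scale, volume$spacing, "SUV")
}

#' Extract the VOI voxel sample from a volume
#'
#' Returns the values and 0-based (x, y, z) coordinates of exactly the
#' mask's true voxels, in lexicographic coordinate order (x fastest, then
#' y, then z — the raster storage order), so repeated calls are
#' deterministic.
#'
#' @param volume a `pet_volume`.
#' @param mask a `pet_mask` on the same grid; must be non-empty.
#' @return An object of class `voi_sample`: list with `values` (numeric),
#'   `coords` (integer matrix, n x 3, 0-based), `spacing` (mm).
#' @export
extract_voi <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "pet_mask"))
  if (!identical(dim(mask$flags), dim(volume$values))) {
    stop("mask shape (", paste(dim(mask$flags), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(volume$values), collapse = "x"), ")", call. = FALSE)
  }
  idx <- which(mask$flags)
  if (length(idx) == 0L) {
    stop("mask is empty; cannot extract a VOI sample", call. = FALSE)
  }
  coords <- arrayInd(idx, dim(mask$flags)) - 1L
  colnames(coords) <- c("x", "y", "z")
  structure(
    list(values = as.numeric(volume$values[idx]),
         coords = coords,
         spacing = volume$spacing),
    class = "voi_sample"
  )
}

#' @export
print.voi_sample <- function(x, ...) {
  cat(sprintf("<voi_sample> %d voxels, %.3f ml, SUV range [%.3g, %.3g]\n",
              length(x$values), voi_volume_ml(x),
              min(x$values), max(x$values)))
  invisible(x)
}

#' VOI volume in millilitres
#'
#' Voxel count times the voxel volume (product of spacings, mm^3),
#' divided by 1000.
#'
#' @param sample a `voi_sample` from [extract_voi()].
#' @return Volume in ml.
#' @export
voi_volume_ml <- function(sample) {
  stopifnot(inherits(sample, "voi_sample"))
  length(sample$values) * prod(sample$spacing) / 1000
}
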