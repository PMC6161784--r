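#' PET volume container
#'
#' A light container for a 3D PET image: a numeric array plus voxel spacing,
#' grid origin and an intensity unit tag. Values are stored in raster order
#' (first index fastest), the native order of the arrays they are built from,
#' so any voxel-wise extraction is reproducible bit-for-bit.
#'
#' @param values 3D numeric array of voxel intensities.
#' @param spacing_mm numeric length-3, voxel edge lengths in mm
#'   (default `c(5.3, 5.3, 5.0)`, a typical clinical PET grid).
#' @param origin numeric length-3, position of voxel (1,1,1) in mm.
#' @param units intensity unit, `"SUV"` or `"kBq/ml"`.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(values, spacing_mm = c(5.3, 5.3, 5.0),
                       origin = c(0, 0, 0), units = c("SUV", "kBq/ml")) {
  units <- match.arg(units)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array, got dimensionality ",
         if (is.array(values)) length(dim(values)) else 1L)
  if (!all(is.finite(values))) stop("voxel values must all be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 strictly positive numbers")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin = as.numeric(origin), units = units),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pet_volume> %d x %d x %d voxels, spacing %s mm, units %s\n",
              d[1], d[2], d[3], paste(format(x$spacing_mm), collapse = " x "),
              x$units))
  invisible(x)
}

#' Binary volume-of-interest mask
#'
#' @param mask 3D array coercible to logical, same grid as its parent volume.
#' @param patient_id patient identifier.
#' @param site lesion site, one of `"bone"`, `"lymph_node"`, `"other"`.
#' @param lesion_id lesion identifier within patient/site.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, patient_id = NA_character_,
                     site = c("bone", "lymph_node", "other"), lesion_id = 1L) {
  site <- match.arg(site)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3D array, got dimensionality ",
         if (is.array(mask)) length(dim(mask)) else 1L)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask contains values not coercible to logical")
  if (!any(mask)) stop("mask has no foreground voxel")
  structure(list(mask = mask, patient_id = as.character(patient_id),
                 site = site, lesion_id = lesion_id),
            class = "voi_mask")
}

voxel_volume_cm3 <- function(spacing_mm) prod(spacing_mm) / 1000

#' Write / read a PET volume as NIfTI-1
#'
#' Values are stored as float64 so a write/read cycle is bit-exact; spacing
#' is carried in the NIfTI `pixdim` field. Masks round-trip through the same
#' functions as 0/1 volumes.
#'
#' @param vol a [pet_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [pet_volume()].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "pet_volume"))
  img <- RNifti::asNifti(vol$values, internal = FALSE)  # float64 payload
  RNifti::pixdim(img) <- vol$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param path path to a NIfTI-1 file with a 3D payload.
#' @param units unit tag to attach on read (NIfTI carries no activity units).
#' @rdname write_volume
#' @export
read_volume <- function(path, units = c("SUV", "kBq/ml")) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim = dim(img))   # plain array, no image attrs
  # trailing singleton dims (e.g. 3D image stored with dim[0]=4) are dropped
  d <- dim(a)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(a) <- d
  }
  if (length(dim(a)) != 3L)
    stop("NIfTI payload in '", path, "' is ", length(dim(a)),
         "-dimensional; expected a 3D volume")
  pet_volume(a, spacing_mm = RNifti::pixdim(img)[1:3], units = units)
}

#' Convert an activity-concentration volume to SUV
#'
#' The standardized uptake value normalizes tissue activity concentration by
#' injected activity per unit body mass:
#' `SUV = concentration[Bq/ml] * body_weight[g] / injected_activity[Bq]`.
#' Decay correction is assumed to have been applied upstream.
#'
#' @param vol a [pet_volume()] with units `"kBq/ml"`.
#' @param body_weight_g body weight in grams (> 0).
#' @param injected_activity_MBq injected activity in MBq (> 0).
#' @return A [pet_volume()] in SUV units.
#' @export
suv_convert <- function(vol, body_weight_g, injected_activity_MBq) {
  stopifnot(inherits(vol, "pet_volume"))
  if (vol$units != "kBq/ml")
    stop("volume is already in ", vol$units, "; expected kBq/ml")
  if (!is.finite(body_weight_g) || body_weight_g <= 0)
    stop("'body_weight_g' must be strictly positive")
  if (!is.finite(injected_activity_MBq) || injected_activity_MBq <= 0)
    stop("'injected_activity_MBq' must be strictly positive")
  bq_ml <- vol$values * 1000              # kBq/ml -> Bq/ml
  suv <- bq_ml * body_weight_g / (injected_activity_MBq * 1e6)
  pet_volume(suv, vol$spacing_mm, vol$origin, units = "SUV")
}

#' Extract the voxel sample of one VOI
#'
#' Returns the SUVs of the foreground voxels in fixed raster order (first
#' array index fastest), together with voxel and lesion volume.
#'
#' @param vol a [pet_volume()].
#' @param voi a [voi_mask()] on the same grid.
#' @return A list of class `voi_sample` with `suv_values`,
#'   `voxel_volume_cm3` and `volume_cm3`.
#' @export
extract_voi <- function(vol, voi) {
  stopifnot(inherits(vol, "pet_volume"), inherits(voi, "voi_mask"))
  if (!identical(dim(vol$values), dim(voi$mask)))
    stop("mask grid ", paste(dim(voi$mask), collapse = "x"),
         " does not match volume grid ", paste(dim(vol$values), collapse = "x"))
  vals <- vol$values[voi$mask]            # logical indexing = raster order
  vv <- voxel_volume_cm3(vol$spacing_mm)
  structure(list(suv_values = vals, voxel_volume_cm3 = vv,
                 volume_cm3 = length(vals) * vv),
            class = "voi_sample")
}

#' Number of whole voxels in a physical volume
#'
#' @param volume_cm3 physical volume in cm^3 (> 0).
#' @param spacing_mm voxel spacing in mm.
#' @return `floor(volume_cm3 / voxel_volume_cm3)`, e.g. a 7.8 cm^3 lesion on
#'   a 5 mm isotropic grid contains 62 voxels.
#' @export
volume_to_voxels <- function(volume_cm3, spacing_mm = c(5, 5, 5)) {
  if (!is.finite(volume_cm3) || volume_cm3 <= 0)
    stop("'volume_cm3' must be strictly positive")
  spacing_mm <- as.numeric(spacing_mm)
  if (any(spacing_mm <= 0)) stop("spacing must be strictly positive")
  as.integer(floor(volume_cm3 / voxel_volume_cm3(spacing_mm)))
}

#' Read a clinical pre/post marker table
#'
#' Comma-separated, "." decimal, UTF-8, header required with columns
#' `patient_id,site,lesion_id,pre_psa,post_psa,pre_ap,post_ap,pre_bap,
#' post_bap,ecog_pre,ecog_post` (one row per patient is also accepted when
#' lesion columns are absent).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!"patient_id" %in% names(df))
    stop("clinical table must contain a 'patient_id' column")
  df
}
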