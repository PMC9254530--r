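#' Write an SUV volume or mask to NIfTI
#'
#' Volumes are written as float64 so that a write/read round trip
#' reproduces the in-memory array exactly; masks are written as 0/1.
#'
#' @param x an [suv_volume()] or [tumour_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  vals <- if (inherits(x, "tumour_mask")) x$values * 1 else x$values
  attr(vals, "pixdim") <- x$spacing
  img <- RNifti::asNifti(vals, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a PET volume in SUV units from NIfTI
#'
#' @param path path to a 3D scalar NIfTI image.
#' @return An [suv_volume()]. 4D inputs and negative values are rejected:
#'   a negative voxel indicates the image is not in SUV units.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D scalar image, got ", length(d), "D: ", path)
  vals <- array(as.numeric(img), dim = d)
  if (min(vals) < 0)
    stop("image contains negative values (min ", signif(min(vals), 4),
         "); not an SUV image: ", path)
  suv_volume(vals, spacing = RNifti::pixdim(img)[1:3])
}

#' Read a tumour mask from NIfTI, paired to a volume
#'
#' Non-zero voxels are inside. The mask must be voxel-aligned to `volume`
#' (same grid, spacing within 1e-3 mm); geometry mismatch is an error,
#' never a silent resample.
#'
#' @param path path to the mask image.
#' @param volume the [suv_volume()] the mask belongs to.
#' @param label delineation label, see [tumour_mask()].
#' @return A [tumour_mask()].
#' @export
read_mask <- function(path, volume, label = "total_lesion") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D mask, got ", length(d), "D: ", path)
  m <- tumour_mask(array(as.numeric(img), dim = d),
                   spacing = RNifti::pixdim(img)[1:3], label = label)
  validate_geometry(volume, m)
  m
}

#' Acquisition metadata for SUV conversion
#'
#' @param injected_dose_mbq injected activity in MBq (> 0).
#' @param body_weight_kg patient weight in kg (> 0).
#' @param injection_time,scan_time `POSIXct` or ISO-8601 strings;
#'   `scan_time` must not precede `injection_time`.
#' @param half_life_min isotope half-life in minutes. Default 109.77
#'   (fluorine-18).
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_dose_mbq, body_weight_kg,
                             injection_time, scan_time,
                             half_life_min = 109.77) {
  if (injected_dose_mbq <= 0) stop("injected dose must be > 0 MBq")
  if (body_weight_kg <= 0) stop("body weight must be > 0 kg")
  if (half_life_min <= 0) stop("half-life must be > 0 min")
  fmt <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")
  inj <- as.POSIXct(injection_time, tz = "UTC", tryFormats = fmt)
  scn <- as.POSIXct(scan_time, tz = "UTC", tryFormats = fmt)
  if (is.na(inj) || is.na(scn)) stop("could not parse timestamps")
  if (scn < inj) stop("scan_time precedes injection_time")
  structure(list(injected_dose_mbq = injected_dose_mbq,
                 body_weight_kg = body_weight_kg,
                 injection_time = inj, scan_time = scn,
                 half_life_min = half_life_min),
            class = "acquisition_meta")
}

#' Read/write acquisition metadata as JSON
#' @param meta an [acquisition_meta()].
#' @param path JSON path.
#' @return `read_meta` returns an [acquisition_meta()].
#' @export
write_meta <- function(meta, path) {
  jsonlite::write_json(list(
    injected_dose_mbq = meta$injected_dose_mbq,
    body_weight_kg = meta$body_weight_kg,
    injection_time = format(meta$injection_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    scan_time = format(meta$scan_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    half_life_min = meta$half_life_min
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_meta
#' @export
read_meta <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisition_meta(x$injected_dose_mbq, x$body_weight_kg,
                   x$injection_time, x$scan_time, x$half_life_min)
}

#' Convert an activity-concentration image to SUV
#'
#' Body-weight SUV: `SUV = C / (D / m)` with tissue concentration `C` in
#' kBq/mL, decay-corrected injected dose `D` in kBq and body mass `m` in
#' grams (1 mL of tissue is taken as 1 g). The dose is decayed from
#' injection to scan time by `2^(-dt / half_life)`; set
#' `decay_to = "injection"` to skip the correction when the scanner
#' already reports concentrations decay-corrected to injection time.
#'
#' @param volume an [suv_volume()] container whose `values` hold activity
#'   concentration in kBq/mL.
#' @param meta an [acquisition_meta()].
#' @param decay_to `"scan"` (default) decays the dose to scan time;
#'   `"injection"` uses the injected dose as-is.
#' @return An [suv_volume()] in SUV units, same geometry.
#' @export
activity_to_suv <- function(volume, meta, decay_to = c("scan", "injection")) {
  stopifnot(inherits(volume, "suv_volume"), inherits(meta, "acquisition_meta"))
  decay_to <- match.arg(decay_to)
  dose_kbq <- meta$injected_dose_mbq * 1000
  if (decay_to == "scan") {
    dt_min <- as.numeric(difftime(meta$scan_time, meta$injection_time,
                                  units = "mins"))
    dose_kbq <- dose_kbq * 2^(-dt_min / meta$half_life_min)
  }
  mass_g <- meta$body_weight_kg * 1000
  suv_volume(volume$values / (dose_kbq / mass_g),
             spacing = volume$spacing, origin = volume$origin)
}
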