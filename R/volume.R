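#' SUV volume container
#'
#' A 3D voxel grid of standardized uptake values (SUV, dimensionless,
#' body-weight normalised) together with its physical geometry. Voxel
#' indices are 0-based in all user-facing coordinates; world coordinates
#' are `origin + index * spacing` (mm), i.e. the position of the voxel
#' centre.
#'
#' @param values 3D numeric array of SUVs; all values must be >= 0.
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin numeric length-3, world position (mm) of voxel (0,0,0).
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ", length(dim(values)), " dims")
  if (anyNA(values)) stop("SUV values must not contain NA")
  if (min(values) < 0) stop("SUV values must be >= 0 (min was ",
                            signif(min(values), 4), ")")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm")
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "suv_volume"
  )
}

#' Tumour mask container
#'
#' Binary voxel mask aligned to an [suv_volume()] (same shape and spacing).
#' `label` records which delineation the mask represents: the manually
#' drawn total lesion or the 40%-of-SUVmax threshold region derived from it.
#'
#' @param values 3D array coercible to logical; non-zero means inside.
#' @param spacing numeric length-3 voxel spacing in mm (must match the
#'   paired volume's).
#' @param label one of `"total_lesion"`, `"threshold_40"`.
#' @return An object of class `tumour_mask`.
#' @export
tumour_mask <- function(values, spacing, label = c("total_lesion", "threshold_40")) {
  label <- match.arg(label)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("mask `values` must be a 3D array")
  v <- array(as.logical(values != 0), dim = dim(values))
  if (!any(v)) stop("mask is empty: no voxel is inside the lesion")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm")
  structure(list(values = v, spacing = spacing, label = label),
            class = "tumour_mask")
}

#' Check that a mask is voxel-aligned to a volume
#'
#' Masks are never resampled: any shape mismatch or spacing difference
#' beyond `tol` mm is an error.
#'
#' @param volume an [suv_volume()].
#' @param mask a [tumour_mask()].
#' @param tol spacing tolerance in mm (default 1e-3).
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
validate_geometry <- function(volume, mask, tol = 1e-3) {
  stopifnot(inherits(volume, "suv_volume"), inherits(mask, "tumour_mask"))
  if (!identical(dim(volume$values), dim(mask$values)))
    stop("geometry mismatch: volume grid is ",
         paste(dim(volume$values), collapse = "x"), " but mask grid is ",
         paste(dim(mask$values), collapse = "x"))
  if (any(abs(volume$spacing - mask$spacing) > tol))
    stop("geometry mismatch: voxel spacing differs by more than ", tol,
         " mm (volume ", paste(volume$spacing, collapse = "/"),
         ", mask ", paste(mask$spacing, collapse = "/"), ")")
  invisible(TRUE)
}

#' @export
print.suv_volume <- function(x, ...) {
  cat("<suv_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "/"), " mm, SUV range [",
      signif(min(x$values), 4), ", ", signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.tumour_mask <- function(x, ...) {
  cat("<tumour_mask:", x$label, "> ", sum(x$values), " of ",
      length(x$values), " voxels inside\n", sep = "")
  invisible(x)
}
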