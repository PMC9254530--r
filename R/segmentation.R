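#' Threshold segmentation at a fraction of SUVmax
#'
#' Derives the threshold delineation from the manually drawn total-lesion
#' mask: `suv_max_used` is the maximum SUV over the total mask, and the
#' threshold mask keeps the total-mask voxels with
#' `SUV >= fraction * suv_max_used`. The comparison is inclusive, so the
#' maximal voxel always survives and the mask is never empty. The threshold
#' is applied only within the total mask (an unrestricted threshold would
#' capture physiologic uptake elsewhere in the field of view) and all
#' supra-threshold voxels are kept, islands included.
#'
#' @param volume an [suv_volume()].
#' @param total_mask the total-lesion [tumour_mask()].
#' @param fraction threshold as a fraction of SUVmax, in (0,1); default 0.40.
#' @return A list of class `segmentation_result`: `total_mask`,
#'   `threshold_mask` (label `threshold_40`), `threshold_fraction`,
#'   `suv_max_used`.
#' @export
threshold_segment <- function(volume, total_mask, fraction = 0.40) {
  validate_geometry(volume, total_mask)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  suv_max_used <- max(volume$values[total_mask$values])
  keep <- total_mask$values & (volume$values >= fraction * suv_max_used)
  structure(list(
    total_mask = total_mask,
    threshold_mask = tumour_mask(keep, spacing = total_mask$spacing,
                                 label = "threshold_40"),
    threshold_fraction = fraction,
    suv_max_used = suv_max_used
  ), class = "segmentation_result")
}
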