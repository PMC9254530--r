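#' Semi-quantitative metabolic profile of a lesion
#'
#' Computes SUVmax, SUVmean and SUVpeak over the masked voxels, the
#' metabolic tumour volume MTV (voxel count times voxel volume, in mL) and
#' the total lesion glycolysis TLG = MTV x SUVmean of the same region.
#' When a threshold region is profiled, its own SUVmean enters its TLG.
#'
#' @param volume an [suv_volume()].
#' @param mask a [tumour_mask()] aligned to `volume`.
#' @param sphere_volume_cm3 SUVpeak sphere volume in cm^3 (default 1.0).
#' @param restrict_peak_to_mask see [suv_peak()].
#' @return A list of class `metabolic_profile`: `suv_max`, `suv_mean`,
#'   `suv_peak`, `mtv_ml`, `tlg`, `n_voxels`, `segmentation_label`.
#' @export
compute_profile <- function(volume, mask, sphere_volume_cm3 = 1.0,
                            restrict_peak_to_mask = FALSE) {
  validate_geometry(volume, mask)
  suv <- volume$values[mask$values]
  voxel_ml <- prod(volume$spacing) / 1000
  mtv_ml <- length(suv) * voxel_ml
  suv_mean <- mean(suv)
  structure(list(
    suv_max = max(suv),
    suv_mean = suv_mean,
    suv_peak = suv_peak(volume, mask, sphere_volume_cm3 = sphere_volume_cm3,
                        restrict_to_mask = restrict_peak_to_mask),
    mtv_ml = mtv_ml,
    tlg = mtv_ml * suv_mean,
    n_voxels = length(suv),
    segmentation_label = mask$label
  ), class = "metabolic_profile")
}

#' SUVpeak: maximal sphere-averaged SUV
#'
#' For every candidate centre voxel inside the mask, averages the SUV of
#' all image voxels whose centres lie within the radius of a sphere of
#' `sphere_volume_cm3` (1.0 cm^3 gives r = (3000/4pi)^(1/3) ~ 6.2035 mm),
#' and returns the maximum such average. Voxels are counted 0/1 by
#' centre-in-sphere; parts of the sphere outside the image contribute
#' nothing (the average is over the voxels present). By default the sphere
#' may extend beyond the tumour mask — only the centre is constrained to
#' it — matching the fixed-volume definition; `restrict_to_mask = TRUE`
#' averages over mask voxels only.
#'
#' @inheritParams compute_profile
#' @param restrict_to_mask if `TRUE`, only mask voxels contribute to the
#'   sphere average.
#' @return The peak SUV (scalar).
#' @export
suv_peak <- function(volume, mask, sphere_volume_cm3 = 1.0,
                     restrict_to_mask = FALSE) {
  validate_geometry(volume, mask)
  sp <- volume$spacing
  r <- (3 * sphere_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  if (r < max(sp) / 2)
    stop("sphere radius ", signif(r, 4), " mm is smaller than half the ",
         "largest voxel dimension; the sphere contains no voxel centre")
  dims <- dim(volume$values)
  maxoff <- floor(r / sp)
  offs <- expand.grid(i = -maxoff[1]:maxoff[1],
                      j = -maxoff[2]:maxoff[2],
                      k = -maxoff[3]:maxoff[3])
  keep <- (offs$i * sp[1])^2 + (offs$j * sp[2])^2 + (offs$k * sp[3])^2 <= r^2
  offs <- offs[keep, , drop = FALSE]
  contrib <- volume$values
  weight <- array(1, dims)
  if (restrict_to_mask) {
    contrib <- contrib * mask$values
    weight <- weight * mask$values
  }
  num <- array(0, dims)
  den <- array(0, dims)
  for (o in seq_len(nrow(offs))) {
    d <- c(offs$i[o], offs$j[o], offs$k[o])
    lo <- pmax(1, 1 - d); hi <- pmin(dims, dims - d)
    if (any(lo > hi)) next
    src1 <- lo[1]:hi[1]; src2 <- lo[2]:hi[2]; src3 <- lo[3]:hi[3]
    dst1 <- src1 + d[1]; dst2 <- src2 + d[2]; dst3 <- src3 + d[3]
    num[dst1, dst2, dst3] <- num[dst1, dst2, dst3] + contrib[src1, src2, src3]
    den[dst1, dst2, dst3] <- den[dst1, dst2, dst3] + weight[src1, src2, src3]
  }
  cand <- mask$values & den > 0
  if (!any(cand)) stop("no candidate sphere contains any voxel")
  max(num[cand] / den[cand])
}

#' One-row summary of a metabolic profile
#'
#' @param profile a `metabolic_profile`.
#' @param id lesion/patient identifier.
#' @return A one-row `data.frame` with a stable column order: `id`,
#'   `segmentation_label`, `suv_max`, `suv_mean`, `suv_peak`, `mtv_ml`,
#'   `tlg`.
#' @export
profile_row <- function(profile, id = NA_character_) {
  data.frame(id = id, segmentation_label = profile$segmentation_label,
             suv_max = profile$suv_max, suv_mean = profile$suv_mean,
             suv_peak = profile$suv_peak, mtv_ml = profile$mtv_ml,
             tlg = profile$tlg, stringsAsFactors = FALSE)
}

#' @export
print.metabolic_profile <- function(x, ...) {
  cat("<metabolic_profile:", x$segmentation_label, ">\n",
      sprintf("  SUVmax %.3f  SUVmean %.3f  SUVpeak %.3f\n",
              x$suv_max, x$suv_mean, x$suv_peak),
      sprintf("  MTV %.2f mL  TLG %.2f\n", x$mtv_ml, x$tlg), sep = "")
  invisible(x)
}
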