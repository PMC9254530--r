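#' Cumulative SUV-volume histogram of a lesion
#'
#' The CSH plots, against each threshold expressed as a fraction `t` of
#' SUVmax, the fraction of lesion volume whose SUV is at least
#' `t * suv_max_ref`. The comparison is inclusive (`>=`), matching the
#' segmentation tie rule, so the curve starts at 1 and the maximal voxel
#' keeps the final point above zero.
#'
#' `suv_max_ref` defaults to the maximum over the supplied mask. For the
#' 40%-threshold region pass the total-lesion SUVmax (from
#' [threshold_segment()]`$suv_max_used`) so the two curves share a
#' reference; since the threshold region contains the maximal voxel the two
#' choices coincide numerically.
#'
#' @param volume an [suv_volume()].
#' @param mask a [tumour_mask()].
#' @param n_bins number of threshold intervals (>= 10); thresholds are
#'   `seq(0, 1, length.out = n_bins + 1)`.
#' @param suv_max_ref reference SUVmax; default `max` over `mask`.
#' @return An object of class `csh_curve`: `thresholds`, `fractions`,
#'   `n_bins`, `suv_max_ref`, `suv_mean` (region mean, used for the exact
#'   area), `n_voxels`, `segmentation_label`.
#' @export
compute_csh <- function(volume, mask, n_bins = 1000, suv_max_ref = NULL) {
  validate_geometry(volume, mask)
  if (n_bins < 10) stop("n_bins must be >= 10")
  suv <- sort(volume$values[mask$values])
  if (is.null(suv_max_ref)) suv_max_ref <- suv[length(suv)]
  if (suv_max_ref <= 0) stop("suv_max_ref must be > 0")
  thresholds <- seq(0, 1, length.out = n_bins + 1)
  n <- length(suv)
  # count of voxels with SUV >= t * ref, via the sorted vector
  below <- findInterval(thresholds * suv_max_ref, suv, left.open = TRUE)
  structure(list(thresholds = thresholds, fractions = (n - below) / n,
                 n_bins = as.integer(n_bins), suv_max_ref = suv_max_ref,
                 suv_mean = mean(suv), n_voxels = n,
                 segmentation_label = mask$label),
            class = "csh_curve")
}

#' AUC of the cumulative SUV-volume histogram (heterogeneity index)
#'
#' A lower AUC-CSH means a more heterogeneous uptake distribution. Two
#' values are reported: the trapezoidal area of the binned curve
#' (`auc_trapezoid`) and the exact bin-free value (`auc_exact`), which by
#' the continuous-histogram identity equals the region SUVmean divided by
#' the reference SUVmax — the integral over t of the volume fraction with
#' SUV >= t*SUVmax is E[SUV]/SUVmax for SUV in [0, SUVmax]. Reporting both
#' bounds the discretisation error, which is at most `2 / n_bins`.
#'
#' @param curve a `csh_curve` from [compute_csh()].
#' @return A list of class `auc_csh_result`: `auc_trapezoid`, `auc_exact`,
#'   `n_bins`, `segmentation_label`.
#' @export
auc_csh <- function(curve) {
  stopifnot(inherits(curve, "csh_curve"))
  f <- curve$fractions
  t <- curve$thresholds
  structure(list(
    auc_trapezoid = sum(diff(t) * (f[-1] + f[-length(f)]) / 2),
    auc_exact = curve$suv_mean / curve$suv_max_ref,
    n_bins = curve$n_bins,
    segmentation_label = curve$segmentation_label
  ), class = "auc_csh_result")
}

#' AUC-CSH from published summary parameters
#'
#' The continuous-histogram identity lets the index be recovered from the
#' standard reported parameters alone: AUC-CSH = SUVmean / SUVmax with
#' SUVmean = TLG / MTV. Useful for cross-checking reported per-lesion
#' values without voxel data.
#'
#' @param tlg total lesion glycolysis of the region.
#' @param mtv metabolic tumour volume of the region (same units as in
#'   `tlg`).
#' @param suv_max the lesion SUVmax.
#' @return The implied AUC-CSH.
#' @export
auc_csh_from_summary <- function(tlg, mtv, suv_max) {
  if (any(mtv <= 0) || any(suv_max <= 0)) stop("mtv and suv_max must be > 0")
  (tlg / mtv) / suv_max
}

#' Total-lesion AUC-CSH implied by threshold-region summaries
#'
#' With a shared SUVmax reference, the ratio of the two indices equals the
#' ratio of the two region means, so the SUVmax cancels:
#' `AUC-CSH_total = AUC-CSH_40 * (TLG_total/MTV_total) / (TLG_40/MTV_40)`.
#'
#' @param auc_csh_40 threshold-region index.
#' @param tlg_total,mtv_total total-lesion TLG and MTV.
#' @param tlg_40,mtv_40 threshold-region TLG and MTV.
#' @return The implied total-lesion AUC-CSH.
#' @export
auc_csh_total_from_subset <- function(auc_csh_40, tlg_total, mtv_total,
                                      tlg_40, mtv_40) {
  auc_csh_40 * (tlg_total / mtv_total) / (tlg_40 / mtv_40)
}

#' Full per-lesion heterogeneity work-up under both segmentations
#'
#' Runs the threshold segmentation, profiles the lesion under the
#' total-lesion and threshold masks, and computes both CSH curves (shared
#' SUVmax reference) with their AUC values.
#'
#' @inheritParams threshold_segment
#' @param n_bins CSH bins, see [compute_csh()].
#' @param id lesion identifier carried into `as_row`.
#' @return A list of class `lesion_heterogeneity` with `segmentation`,
#'   `profile_total`, `profile_40`, `csh_total`, `csh_40`, `auc_total`,
#'   `auc_40`, and `row` (one tidy data.frame row of all parameters).
#' @export
lesion_heterogeneity <- function(volume, total_mask, fraction = 0.40,
                                 n_bins = 1000, id = NA_character_) {
  seg <- threshold_segment(volume, total_mask, fraction = fraction)
  p_tot <- compute_profile(volume, seg$total_mask)
  p_40 <- compute_profile(volume, seg$threshold_mask)
  csh_tot <- compute_csh(volume, seg$total_mask, n_bins = n_bins)
  csh_40 <- compute_csh(volume, seg$threshold_mask, n_bins = n_bins,
                        suv_max_ref = seg$suv_max_used)
  a_tot <- auc_csh(csh_tot)
  a_40 <- auc_csh(csh_40)
  row <- data.frame(
    id = id, suv_max = p_tot$suv_max, suv_mean = p_tot$suv_mean,
    suv_peak = p_tot$suv_peak,
    mtv_total = p_tot$mtv_ml, tlg_total = p_tot$tlg,
    mtv_40 = p_40$mtv_ml, tlg_40 = p_40$tlg,
    auccsh_total = a_tot$auc_trapezoid, auccsh_40 = a_40$auc_trapezoid,
    auccsh_total_exact = a_tot$auc_exact, auccsh_40_exact = a_40$auc_exact,
    stringsAsFactors = FALSE)
  structure(list(segmentation = seg, profile_total = p_tot, profile_40 = p_40,
                 csh_total = csh_tot, csh_40 = csh_40,
                 auc_total = a_tot, auc_40 = a_40, row = row),
            class = "lesion_heterogeneity")
}

#' Export a CSH curve as a data.frame (threshold, fraction)
#' @param curve a `csh_curve`.
#' @return A `data.frame` with columns `threshold` and `volume_fraction`.
#' @export
csh_as_data_frame <- function(curve) {
  data.frame(threshold = curve$thresholds, volume_fraction = curve$fractions)
}

#' Compare the two segmentation methods across a cohort of lesions
#'
#' For each paired parameter (MTV, TLG, AUC-CSH) computes a Wilcoxon
#' signed-rank paired test, the Spearman correlation between methods, and
#' descriptive summaries (median with IQR and mean +/- sd) per method.
#' All-zero paired differences make the signed-rank test degenerate; that
#' case is reported via the `note` column rather than an error.
#'
#' @param lesions data.frame with paired columns `mtv_total`, `mtv_40`,
#'   `tlg_total`, `tlg_40`, `auccsh_total`, `auccsh_40` (one row per
#'   lesion), e.g. stacked `row`s from [lesion_heterogeneity()].
#' @return A data.frame, one row per parameter, with test statistics,
#'   p-values, Spearman rho, and descriptives.
#' @export
compare_segmentations <- function(lesions) {
  pairs <- list(MTV = c("mtv_total", "mtv_40"),
                TLG = c("tlg_total", "tlg_40"),
                AUC_CSH = c("auccsh_total", "auccsh_40"))
  need <- unlist(pairs)
  if (!all(need %in% names(lesions)))
    stop("missing paired columns: ",
         paste(setdiff(need, names(lesions)), collapse = ", "))
  if (nrow(lesions) < 3) stop("need at least 3 paired observations")
  rows <- lapply(names(pairs), function(nm) {
    x <- lesions[[pairs[[nm]][1]]]  # total
    y <- lesions[[pairs[[nm]][2]]]  # threshold
    if (anyNA(x) || anyNA(y)) stop("paired values contain NA for ", nm)
    note <- ""
    if (all(x == y)) {
      w_stat <- NA_real_; w_p <- NA_real_
      note <- "degenerate: all paired differences are zero"
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                exact = FALSE, correct = TRUE))
      w_stat <- unname(wt$statistic); w_p <- wt$p.value
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(
      parameter = nm, n = length(x),
      total_median = stats::median(x), total_q1 = unname(stats::quantile(x, .25)),
      total_q3 = unname(stats::quantile(x, .75)),
      total_mean = mean(x), total_sd = stats::sd(x),
      thr_median = stats::median(y), thr_q1 = unname(stats::quantile(y, .25)),
      thr_q3 = unname(stats::quantile(y, .75)),
      thr_mean = mean(y), thr_sd = stats::sd(y),
      signed_rank_V = w_stat, signed_rank_p = w_p,
      spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
      note = note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
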