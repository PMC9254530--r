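#!/usr/bin/env Rscript
# Validates the voxel pipeline against the closed-form truths of the five
# phantom profiles, at two voxel sizes, and records the discretisation
# error of AUC-CSH, MTV and SUVpeak. Writes results/phantom_validation.csv.

suppressPackageStartupMessages(library(pethet))
dir.create("results", showWarnings = FALSE)

kinds <- c("homogeneous", "two_level", "radial_linear", "necrotic_core",
           "uniform_histogram")
rows <- list()
for (kind in kinds) {
  for (spacing in c(2, 1)) {
    ph <- generate_phantom(phantom_spec(
      grid_shape = rep(2 * ceiling(27 / spacing) + 1, 3),
      voxel_spacing = rep(spacing, 3), tumour_radius = 25,
      profile_kind = kind))
    prof <- compute_profile(ph$volume, ph$mask)
    a <- auc_csh(compute_csh(ph$volume, ph$mask))
    rows[[length(rows) + 1]] <- data.frame(
      profile = kind, spacing_mm = spacing, n_voxels = prof$n_voxels,
      auc_exact = a$auc_exact, auc_trapezoid = a$auc_trapezoid,
      auc_truth = ph$truth$auc_csh,
      auc_abs_err = abs(a$auc_exact - ph$truth$auc_csh),
      mtv_ml = prof$mtv_ml, mtv_truth = ph$truth$mtv_ml,
      mtv_rel_err = abs(prof$mtv_ml - ph$truth$mtv_ml) / ph$truth$mtv_ml,
      suv_peak = prof$suv_peak, suv_peak_truth = ph$truth$suv_peak)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/phantom_validation.csv", row.names = FALSE)

cat("Phantom validation (R = 25 mm lesions):\n")
print(tab[, c("profile", "spacing_mm", "auc_truth", "auc_exact",
              "auc_abs_err", "mtv_rel_err")], digits = 4, row.names = FALSE)
cat(sprintf("\nLargest AUC-CSH error: %.4f at 2 mm, %.4f at 1 mm\n",
            max(tab$auc_abs_err[tab$spacing_mm == 2]),
            max(tab$auc_abs_err[tab$spacing_mm == 1])))
cat("MTV error shrinks with voxel size for every profile:",
    all(tapply(tab$mtv_rel_err, tab$profile, diff) < 0), "\n")
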