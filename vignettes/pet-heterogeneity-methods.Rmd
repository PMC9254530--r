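---
title: "Quantifying intra-tumoural metabolic heterogeneity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-tumoural metabolic heterogeneity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pethet)
```

This vignette records how the package's quantities are defined, the
conventions adopted where the field leaves room, and what the simulation
layers do and do not establish.

## The heterogeneity index

For a lesion with voxel SUVs bounded by its SUVmax, the cumulative
SUV-volume histogram is the non-increasing curve
$F(t) = \Pr(\mathrm{SUV} \ge t \cdot \mathrm{SUVmax})$ over the volume,
for $t \in [0,1]$, and the heterogeneity index is its area,
$\mathrm{AUC\text{-}CSH} = \int_0^1 F(t)\,dt$. Lower values mean a more
heterogeneous uptake distribution. Two properties drive the design:

* **Exact value.** Since SUV lies in $[0, \mathrm{SUVmax}]$, Fubini gives
  $\int_0^1 F(t)\,dt = \mathbb{E}[\mathrm{SUV}]/\mathrm{SUVmax}$. The
  package always reports this bin-free value (`auc_exact`) next to the
  trapezoidal area of the binned curve (`auc_trapezoid`). The binning used
  by clinical workstations is typically unreported; reporting both bounds
  the discrepancy, which is at most $2/n_\mathrm{bins}$ and in practice
  below 0.002 at the default `n_bins = 1000`.
* **Histogram-only dependence.** The index depends only on the SUV
  histogram of the region, so it is invariant under voxel permutation and
  under rescaling of all SUVs — both enforced as property tests.

Thresholding is **inclusive** (`>=`) everywhere — in the CSH counts and in
the 40% segmentation — so the maximal voxel always qualifies, $F(1) > 0$,
and the threshold mask is never empty. This is a convention; the tie rule
used by the original clinical software is unknowable from reported values,
and ties only matter on measure-zero threshold sets.

### Two segmentations, one reference

The index is computed for the full manually drawn lesion
(`total_lesion`) and for the 40%-of-SUVmax threshold region
(`threshold_40`) derived from it inside the total mask. The threshold
region's CSH uses the **total-lesion SUVmax as its reference**. Because
the threshold region contains the maximal voxel this equals the
region-local maximum, but making the shared reference explicit yields the
subset-mean inequality
$\mathrm{AUC\text{-}CSH}_{40} \ge \mathrm{AUC\text{-}CSH}_{total}$
(the mean over a supra-threshold subset cannot be below the whole-region
mean), and the useful cancellation
$$\mathrm{AUC\text{-}CSH}_{total} = \mathrm{AUC\text{-}CSH}_{40}
 \cdot \frac{TLG_{total}/MTV_{total}}{TLG_{40}/MTV_{40}},$$
which lets published per-lesion values be cross-checked without voxel
data (`auc_csh_from_summary()`, `auc_csh_total_from_subset()`). The
+/- 0.015 tolerance used in those cross-checks covers the source
software's unknown binning plus two-to-three-decimal rounding of the
printed parameters.

### Semi-quantitative parameters

* **MTV** (mL) is voxel count × voxel volume; no partial-volume weighting.
* **TLG** is MTV × SUVmean **of the same region** — the threshold region's
  TLG uses the threshold region's mean. The common notation
  "MTV₄₀ × SUVmean" is ambiguous on this point; the region-specific
  convention is the one under which published paired worked examples are
  mutually consistent, which the acceptance checks verify.
* **SUVpeak** is the maximal average over a 1.0 cm³ sphere
  (r ≈ 6.2035 mm) centred on a lesion voxel. Voxels count 0/1 by
  centre-in-sphere (deterministic and oracle-checkable: on a 4 mm
  isotropic grid the sphere holds exactly 19 voxel centres). By default
  the sphere may extend beyond the mask — only its centre is constrained —
  matching the fixed-volume definition; `restrict_to_mask = TRUE` gives
  the alternative. Spheres truncated by the image border average over the
  voxels present. A sphere smaller than half the largest voxel dimension
  is an error.

### Image I/O and SUV conversion

Volumes and masks are NIfTI; masks are binarised (non-zero = inside) and
must be voxel-aligned to their volume (same grid, spacing within
10⁻³ mm) — geometry mismatch is an error, never a silent resample.
Voxel indices are 0-based; world coordinates are `origin + index ×
spacing` (mm). SUV is body-weight normalised:
`SUV = C / (D / m)` with concentration `C` in kBq/mL, decay-corrected
dose `D` in kBq and mass `m` in grams (1 mL ≡ 1 g). The ¹⁸F half-life is
fixed at 109.77 min. Whether a site decay-corrects the dose to scan time
or reports concentrations already corrected to injection differs between
vendors; both conventions are computable (`decay_to = "scan"` is the
default, `"injection"` skips the correction).

## Digital phantoms

`generate_phantom()` builds a spherical lesion (radius R mm) in a uniform
background, with voxel membership decided by voxel centre inside the
sphere — simple, exact and testable, at the cost of ignoring partial
volume at the rim. Five radial profiles give closed-form truths
(S = peak SUV):

| profile | SUV(r) | exact AUC-CSH |
|---|---|---|
| homogeneous | S | 1 |
| two_level (volume fraction f at S, rest at αS) | step | f + (1−f)α |
| radial_linear | S(1 − r/R) | 1/4 |
| necrotic_core (core radius fraction c, level βS) | step | c³β + (1 − c³) |
| uniform_histogram | S(1 − (r/R)³) | 1/2 |

`radial_linear` follows from $F(t) = (1-t)^3$; `uniform_histogram` is the
radius mapping whose volume histogram is uniform on (0, S]. The analytic
SUVpeak is reported where the sphere average has a closed form at the
lesion centre (all centre-peaked profiles); for the rim-peaked necrotic
profile the maximising centre has no tractable form and the truth is `NA`.

Noise is additive Gaussian clipped at zero, applied to lesion voxels
only — the simplest stand-in for reconstruction noise; the analytic truth
is always noise-free. The phantoms do **not** emulate PET physics
(scatter, randoms, point-spread blur, reconstruction artefacts),
irregular lesion shapes, or physiologic background structures, so passing
phantom tests demonstrates correctness of the *measurement pipeline*, not
robustness to scanner effects.

Discretisation: voxelised AUC-CSH and MTV converge to the closed forms as
spacing shrinks (checked at 2 mm vs 1 mm). One subtlety is worth
recording: the index's reference is the *observed* voxel maximum, so if
the grid places no voxel at the profile peak (e.g. an even grid whose
centre falls between voxels) the observed SUVmax under-reads the true
peak and the index is biased upward by a factor ≈ S/ŝ_max. Validation
phantoms therefore use odd grids with the lesion centred on a voxel;
clinical lesions, whose peak is not a single mathematical point, are not
affected by this artefact of idealised profiles.

## The simulated cohort

`cohort_spec()` defaults encode the study conditions of a 38-patient
newly diagnosed paediatric neuroblastoma cohort: age 3.636 ± 2.166 y,
14/38 male, 34/38 abdominal primaries, INSS stages 2/1/6/29, COG risk
2/14/22, a 19/38 event rate, and follow-up censored uniformly on
(0, 33.4] months (the reported follow-up range). Prevalences the study
did not report are set once to field-plausible values and flagged as
unanchored: bone-marrow involvement 0.5, MYCN gain/amplification 0.5,
del(1p) 0.3, del(11q) 0.3. The serum markers (NSE, LDH, PHOX2B) are
lognormal on synthetic scales; their per-unit hazard ratios are ≈ 1 by
construction, as in the clinical tables.

Outcomes follow an exponential proportional-hazards model:
$h_i = h_0 \exp(\beta^\top x_i)$, event time $T_i \sim \mathrm{Exp}(h_i)$,
censor time $C_i \sim U(0, H]$, `event` $= T_i \le C_i$. The Cox model
fitted downstream is semi-parametric and therefore correctly specified
under this generator, giving closed-form truth for recovery tests. The
default planted effect is the bone-marrow-involvement log hazard ratio
$\log(4.677)$, the multivariate estimate reported for that covariate.
When `baseline_hazard` is `NULL`, $h_0$ is calibrated by `uniroot` on the
cohort's own linear predictors so the expected event fraction
$\mathbb{E}[1 - (1 - e^{-hH})/(hH)]$ equals `target_event_fraction`
(default 19/38 ≈ 0.0215 events/month under the defaults).

The heterogeneity indices are then drawn **conditional on the realised
event status** from truncated normals on (0, 1] (total: 0.410 ± 0.062
event vs 0.515 ± 0.101 non-event; 40%: 0.541 ± 0.039 vs 0.581 ± 0.049),
which reproduces the published subgroup statistics by construction. The
design consequence is deliberate: AUC-CSH is prognostic in the simulated
cohort through its event-group linkage rather than through a causal term
in the hazard, so null-calibration tests (type-I error of the log-rank
and subgroup stages) must group on covariates that are outside that
linkage (e.g. bone-marrow involvement with all `log_hr` zero), and
parameter-recovery tests plant effects on hazard covariates. The
remaining imaging features keep the pipeline's internal identities:
`suv_mean = auccsh_total × suv_max` and `tlg = mtv × suv_mean` per region.

What the cohort generator does **not** emulate: correlated covariates
(stage, COG risk and MYCN are independent here but strongly associated in
real neuroblastoma), non-proportional hazards, informative censoring,
multi-lesion patients, and measurement error in the imaging features.
Power and type-I results on this generator are statements about the
pipeline, not about clinical effect sizes.

## Cohort statistics: conventions

* **Cox regression** uses the Breslow tie approximation (the default of
  the statistical software most such studies use). Monotone-likelihood
  warnings are captured into a `diagnostic` column, not raised.
* **Backward elimination** drops the variable with the largest Wald p
  above `p_remove = 0.10` (the common backward-Wald default; the removal
  threshold is configurable), refitting after each removal. `p_remove = 1`
  retains everything, `0` removes everything — boundary behaviour under
  test.
* **AUC-CSH enters the Cox model on its raw (0, 1] scale**, so its hazard
  ratios are "per unit AUC-CSH" and numerically tiny with very wide CIs —
  matching the scale of the published estimates; no rescaling is applied.
* **Subgroup comparisons** use Student's t when both groups pass
  Shapiro–Wilk at α = 0.05, otherwise the Mann–Whitney rank-sum test; the
  paired method comparison uses the Wilcoxon signed-rank test plus
  Spearman correlation. Identical groups are reported as degenerate with
  p = 1 (no evidence of difference) rather than erroring.
* **ROC dichotomisation** maximises Youden's J over the observed values
  with direction "lower is positive" for AUC-CSH (lower index = more
  heterogeneous = worse outcome). J is piecewise constant, so the
  maximiser is an interval; the returned cutoff is the midpoint of the
  tie region, which under perfect separation is the midpoint of the
  class gap. Deterministic and documented, since published studies rarely
  state their tie rule.
* **Risk stratification** on the index cutoff (default 0.49) and
  bone-marrow involvement: Group I neither factor, Group II exactly one,
  Group III both — "or" read exclusively so the groups partition the
  cohort.
* **No multiple-testing correction** is applied anywhere; all p-values
  are raw, as is conventional in these clinical analyses, and should be
  read accordingly.
* Event-free survival is time to the first of relapse, progression or
  death, censored at last follow-up.

## Problem sizes and numerical tolerances

The validation suite uses: R = 25 mm phantoms at 2 mm and 1 mm voxels
(closed-form recovery within 0.01); 50 random lesions of ≤ 500 voxels for
the oracle equivalence of the trapezoidal area at 10⁵ bins against a
sorted-voxel exact integral (10⁻⁶ absolute); a 200-phantom sweep for the
ordering invariants; n = 10⁴ cohorts for hazard-ratio recovery (within
10%); 1000 null replicates at n = 38 for type-I calibration of the
log-rank and subgroup stages (accepted in [0.03, 0.07] at α = 0.05); and
100 seeds at n = 1000 for recovery of the Youden cutoff. The cutoff's
population target is the crossing of the two event-group densities
(≈ 0.476); at n = 1000 the estimator's spread sits inside (0.41, 0.52),
the interval that also brackets the published 0.49, while at the study's
n = 38 the 5–95% spread is wider (reported descriptively by
`analysis/04_survival_analysis.R`).

## Known limitations

Lesions are single spheres; masks are taken as given (no automated
detection, no partial-volume correction); DICOM assembly and PET
reconstruction are out of scope (NIfTI in SUV units, or kBq/mL plus
acquisition metadata, is the entry point); metastatic lesions and
longitudinal scans are not modelled; and the heterogeneity vocabulary is
limited to AUC-CSH — texture features, coefficients of variation and
fractal measures are deliberately excluded.
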