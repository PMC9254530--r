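# pethet

Intra-tumoural metabolic heterogeneity from ¹⁸F-FDG PET, quantified as the
area under the cumulative SUV-volume histogram (AUC-CSH), with the full
downstream survival-analysis pipeline used to evaluate it as a prognostic
imaging biomarker in paediatric neuroblastoma.

## The problem

FDG uptake is rarely uniform across a tumour: necrosis, hypoxia and
variable cellularity make some regions hot and others cold, and more
heterogeneous tumours tend to do worse. Single-number SUV statistics
(SUVmax, SUVmean) ignore this. The cumulative SUV-volume histogram
summarises the whole uptake distribution of a lesion: for each threshold
`t ∈ [0, 1]`, it records the fraction of lesion volume with
`SUV ≥ t · SUVmax`,

```
F(t) = |{ v ∈ lesion : SUV(v) ≥ t · SUVmax }| / |lesion| .
```

The heterogeneity index is the area under this curve,

```
AUC-CSH = ∫₀¹ F(t) dt ,
```

which equals 1 for a perfectly homogeneous lesion and decreases as uptake
becomes more heterogeneous. Because `SUV ∈ [0, SUVmax]` inside the lesion,
the integral has a closed form — `AUC-CSH = SUVmean / SUVmax` over the
region — which the package reports alongside the binned trapezoidal value
and uses to cross-check published per-lesion parameters.

The index is computed under two delineations: the full manually drawn
lesion (`total`) and the 40%-of-SUVmax threshold region derived from it
(`40%`), together with the standard semi-quantitative parameters — SUVmax,
SUVmean, SUVpeak (maximal 1.0 cm³ sphere-averaged SUV), metabolic tumour
volume MTV (mL) and total lesion glycolysis TLG = MTV × SUVmean.

Because clinical PET volumes cannot be redistributed, the package ships
two simulation layers that make every stage testable end to end:

* **digital phantoms** — spherical lesions with five radial uptake
  profiles whose SUVmean, MTV, TLG and AUC-CSH are known in closed form;
* **a simulated cohort generator** — 38-patient neuroblastoma cohorts
  with the published covariate structure, event-conditional AUC-CSH
  distributions, and an exponential proportional-hazards outcome model so
  that planted hazard ratios are recoverable by Cox regression.

The cohort statistics mirror a standard prognostic work-up: baseline and
subgroup comparisons, univariate and backward-stepwise multivariate Cox
regression for event-free survival, Youden-index ROC dichotomisation of
the heterogeneity index, and Kaplan–Meier/log-rank analysis including a
three-group stratification on AUC-CSH and bone-marrow involvement.

## Worked example

```r
library(pethet)

spec <- phantom_spec(grid_shape = c(41, 41, 41), voxel_spacing = c(2, 2, 2),
                     tumour_radius = 30, profile_kind = "necrotic_core",
                     suv_max_true = 6,
                     profile_params = list(core_radius_fraction = 0.6,
                                           core_level_fraction = 0.15),
                     noise_sd = 0.2, seed = 7)
ph <- generate_phantom(spec)
lh <- lesion_heterogeneity(ph$volume, ph$mask, id = "phantom-1")
print(lh$row, digits = 3)
#>          id suv_max suv_mean suv_peak mtv_total tlg_total mtv_40 tlg_40
#> 1 phantom-1    6.76     4.89     6.05       113       554   88.6    532
#>   auccsh_total auccsh_40 auccsh_total_exact auccsh_40_exact
#> 1        0.724     0.888              0.724           0.888
```

A 30 mm lesion with a large necrotic core reads out an MTV of 113 mL and
a total-lesion AUC-CSH of 0.72 — clearly below 1, flagging heterogeneity —
while the 40% threshold region, which drops most of the cold core, is
nearly homogeneous (0.89) and 25 mL smaller. The noise-free closed form
for this profile is 0.816; the difference is the planted voxel noise
(`noise_sd = 0.2` raises the observed SUVmax and widens the histogram).
The exact (`*_exact`, SUVmean/SUVmax) and trapezoidal columns agree to
three decimals at the default 1000 bins.

The cohort layer is driven the same way:

```r
co <- generate_cohort(cohort_spec(seed = 7))          # n = 38
univariate_cox(co, "auccsh_total")                    # per-unit HR, 95% CI, p
roc_optimal_cutoff(co)$cutoff                         # Youden dichotomisation
km_logrank(co, stratify_risk_groups(co, 0.49))$p      # 3-group log-rank
```

## Analysis workflow

The numbered scripts under `analysis/` run the full study on simulated
data and write their tables under `results/`:

1. `01_phantom_validation.R` — voxel pipeline vs closed-form truths at
   two voxel sizes;
2. `02_method_comparison.R` — paired comparison of the two segmentations
   over a 60-lesion sweep (signed-rank, Spearman);
3. `03_cohort_simulation.R` — default cohort, baseline table, subgroup
   comparisons;
4. `04_survival_analysis.R` — Cox screening + backward elimination, ROC
   cutoff, Kaplan–Meier/log-rank stratification, planted-effect recovery.

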