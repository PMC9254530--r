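Package: pethet
Title: Intra-Tumoural Metabolic Heterogeneity from FDG-PET via the
    Cumulative SUV-Volume Histogram
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies intra-tumoural metabolic heterogeneity on
    18F-FDG PET as the area under the cumulative SUV-volume histogram
    (AUC-CSH), alongside the standard semi-quantitative parameters
    (SUVmax, SUVmean, SUVpeak, metabolic tumour volume, total lesion
    glycolysis) under total-lesion and 40%-of-SUVmax threshold
    segmentations. Provides digital spherical phantoms with analytically
    known heterogeneity, a simulated paediatric neuroblastoma cohort
    generator with an exponential proportional-hazards outcome model,
    and the downstream cohort statistics: method comparison, subgroup
    comparison, univariate and backward-stepwise Cox regression for
    event-free survival, Youden-index ROC dichotomisation, and
    Kaplan-Meier/log-rank analysis including a combined two-risk-factor
    stratification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
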