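Package: npqpipe
Title: Quality Control, Biomarker Cutoffs and Progression Modelling for
    Targeted Plasma Proteomics Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis toolkit for targeted plasma proteomics
    panels reported in normalized protein quantification (NPQ) units, as
    used in large mixed-dementia cohorts. Implements interquartile-range
    outlier masking and two-step call-rate filtering, surrogate-variable
    adjusted per-protein differential abundance with false-discovery-rate
    control, cross-disease effect-size comparison with prediction-band
    outlier detection, data-driven biomarker positivity cutoffs (univariate
    two-component Gaussian mixture with equal-posterior threshold, Youden
    index, and dual 95 percent sensitivity/specificity thresholds with an
    intermediate zone), concordance with PET-defined amyloid and tau
    status, covariate-adjusted logistic ROC prediction, progression-to-AD
    proportional-hazards and Kaplan-Meier analysis, APOE epsilon-4
    proteoform concordance, cross-run reproducibility summaries, and a
    seeded synthetic cohort generator that emulates the statistical
    structure of such studies for testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
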