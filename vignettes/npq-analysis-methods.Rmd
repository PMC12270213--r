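---
title: "Methods: from NPQ quality control to biomarker cutoffs and progression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from NPQ quality control to biomarker cutoffs and progression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

npqpipe analyses targeted plasma-proteomics panels reported in normalized
protein quantification (NPQ) units, the kind of CNS disease panel used in
large mixed-dementia cohorts (Alzheimer disease, dementia with Lewy bodies,
frontotemporal dementia, Parkinson disease, and cognitively unimpaired
controls). This vignette is the package's account of the statistical
procedures it implements, the choices that were genuinely open, and what the
synthetic cohort generator does and does not emulate.

```{r setup}
library(npqpipe)
```

## Scales

NPQ is natively log2. The pipeline's container (`npq_matrix`) carries a scale
tag (`log2`, `linear`, `log10`) and `transform_scale()` converts exactly
between them (`linear = 2^log2`, `log10 = log2 * log10(2)`). Differential
abundance, cutoffs and survival models all operate on the log10 scale, the
convention the downstream analyses assume; cutoffs are additionally reported
on the z and linear scales via the stored standardization pair.

## Quality control

QC has three stages, in order:

1. **IQR outlier masking** (`mask_iqr_outliers`): per analyte, values outside
   `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` become missing. Quantiles use linear
   interpolation (type 7, `h = (n - 1)p + 1`); the rule is stated explicitly
   because quantile conventions differ and reproducibility requires fixing
   one. The pass is single-shot — fences are not re-derived after masking.
   Analytes with fewer than four observed values have undefined fences and
   pass through flagged.
2. **Two-step call-rate filtering** (`call_rate_filter`): analytes and then
   samples below a 65% call rate are removed; call rates are recomputed on
   the surviving submatrix; analytes and then samples below 85% are removed.
   The staged recomputation deliberately retains borderline analytes and
   samples that a single 85% pass would discard — a sample observed on 60%
   of the original panel but 100% of the surviving analytes is kept.
   Filtering analytes before samples within each step is a convention (the
   two orders differ only in contrived cases); it is fixed and documented
   rather than configurable guesswork at analysis time.
3. **Descriptive metrics** (`qc_report`): coefficient of variation (sample
   SD over mean on the linear scale) and an optional limit-of-detection
   pass-through. Neither influences which analytes or samples are kept.

Outlier masking is applied per analyte across the whole cohort, not within
diagnosis groups: group-wise masking would erase genuine group shifts.

## Differential abundance with surrogate variables

Per analyte, ordinary least squares of log10 NPQ on a predictor plus age at
draw, sex, and two surrogate variables:

* disease contrasts (`AD_vs_CO`, `DLB_vs_CO`, `FTD_vs_CO`, `PD_vs_CO`) use a
  case indicator with controls as reference and only those two groups'
  samples;
* endophenotype contrasts (amyloid-PET Centiloids, tau-PET SUVR, CSF
  Abeta42/Abeta40, CDR) use the phenotype as a continuous predictor on all
  samples where it is observed. CDR is ordinal; it is modelled as continuous,
  a choice made once and recorded here.

By default one sample per participant enters (the latest draw), matching a
unique-participant analysis; `one_per_participant = FALSE` uses all samples.
P-values are two-sided t-tests on the predictor coefficient;
Benjamini–Hochberg adjustment (`adjust_fdr`, via `stats::p.adjust`) is
applied across analytes within a contrast, with 5% FDR as the significance
convention.

Surrogate variables (`estimate_surrogate_variables`) absorb unmodelled batch
and technical structure. The estimator is a deterministic residual-SVD
approximation to surrogate variable analysis: missing values are imputed by
seeded draws from the same analyte's observed values, each analyte is
regressed on the primary design, residuals are standardized analyte-wise,
and the top sample-space singular vectors are the SVs (mean zero, mutually
orthogonal). The number of SVs is fixed at two by default rather than
estimated by permutation. SVs are estimated per contrast. Two properties are
validated on synthetic cohorts: with planted batch factors the canonical
correlation between SVs and truth exceeds 0.9, and with no batch structure
including SVs moves coefficients by well under half a standard error.

A known limitation of residual-space SVs: they are orthogonal to the design
by construction, so when a strong shared batch factor happens, by sampling
chance, to correlate with diagnosis in a particular cohort draw, that
component is not removable and per-analyte null t-statistics become mildly
over-dispersed. With the true factors supplied in place of SVs the tests are
calibrated; this is a property of the estimator class, not of the
implementation.

## Cross-contrast effect-size comparison

`compare_effect_sizes` correlates the per-protein effect sizes of two
contrasts on the proteins significant in at least one of them (FDR rule by
default; a nominal-p rule for underpowered contrasts), regresses one set of
betas on the other, and flags proteins outside a 95% prediction band or with
discordant signs. The band is a per-point prediction band, not a
mean-confidence band: outliers are individual proteins, and a mean band
would flag nearly everything at large n. Planted discordant proteins
(opposite sign, four residual SDs) are recovered 20/20 times in the test
suite.

## Biomarker positivity cutoffs

Three cutoff schemes for a bimodal biomarker such as plasma p-tau217:

**Gaussian-mixture (single) cutoff.** Log10 values are z-scored using the
mean and SD of all values entering the fit; `fit_two_component_gmm` runs EM
for a two-component univariate mixture with unequal variances. Restart `r`
initializes by splitting the data at its `0.3 + 0.1 r` quantile and taking
moments from each side; the best converged log-likelihood is kept; a
variance floor of `1e-6` prevents component collapse; convergence is a
relative log-likelihood change below `1e-8` (cap 1000 iterations). Unequal
variances are the default because nothing constrains the two modes to share
a spread. The cutoff (`equal_posterior_cutoff`) is the point between the
component means where posterior membership is 50/50, i.e. the root of
`w1 phi(z; mu1, s1) = w2 phi(z; mu2, s2)` — a quadratic in `z`; for equal
variances the closed form `z = (mu1 + mu2)/2 + s^2 log(w1/w2)/(mu2 - mu1)`
applies. When the components are so overlapped that no root lies between the
means, `gmm_cutoff` falls back to the mean midpoint and flags the model
low-confidence (the same flag raised whenever `mu2 - mu1 < s1 + s2`).

**Youden cutoff.** `youden_cutoff` scans the observed scores as candidate
thresholds (no interpolation — reproducible without smoothing choices) and
maximizes sensitivity + specificity − 1 against a reference status, with
ties broken toward the smallest threshold using an integer-valued objective
so floating-point noise cannot reorder ties.

**Dual cutoffs.** `dual_cutoffs` places a lower cutoff at the largest
threshold keeping sensitivity at or above 95% and an upper cutoff at the
smallest threshold with specificity at or above 95%, trichotomizing samples
into low / intermediate / high. The intermediate zone is the closed interval
`[lower, upper]`; interval notation in print rarely specifies endpoint
inclusion, so the choice is fixed here. Concordance against PET status is
evaluated on the low/high classes only (`confusion(..., drop_intermediate =
TRUE)`).

Reference statuses (`pet_reference`): amyloid-PET positive above 20
Centiloids, tau-PET positive above 1.5 SUVR, CSF amyloid-positive below an
Abeta42/Abeta40 ratio of 0.0673. Values exactly at a cutpoint are negative
(strict inequalities).

## Concordance

`confusion` builds 2×2 counts (with intermediates counted and excluded
explicitly), concordance percentage, sensitivity, specificity, PPV and NPV.
Percentages round half-up to two decimals — the convention of printed
confusion tables — via `round_half_up`, since banker's rounding differs on
exact ties. APOE ε4 carrier status is classified from the ε4
proteoform-specific analyte by reusing the mixture cutoff
(`classify_apoe4_from_proteoform`); the proteoform assay's own
classification rule is vendor-side and unspecified, so the mixture cutoff is
this package's convention and is swappable. `genotype_to_apoe4` maps the six
genotypes (ε2/ε2, ε2/ε3, ε3/ε3 negative; ε2/ε4, ε3/ε4, ε4/ε4 positive).

## Predictive models

`fit_logistic_auc` fits a maximum-likelihood logistic regression of the
binary outcome on the feature(s) plus age and sex, scores samples by the
full-model linear predictor, and computes AUC as the Mann–Whitney rank
statistic (midranks for ties). Covariate-adjustment conventions differ
across packages; using the full-model linear predictor as the score is the
documented choice here. The 95% CI is a stratified nonparametric bootstrap
(cases and controls resampled separately, 2,000 replicates, seeded) of the
score AUC without refitting — with a fixed feature set the linear predictor
is monotone in the features, and refitting per replicate would change
nothing for single-feature models while multiplying cost. Perfect
separation is reported as AUC 1 with a flag rather than an error.
`ratio_feature` forms protein ratios as log10 differences.
`horizon_auc` predicts conversion within 5/10/15 years: converters within
the horizon are cases; participants followed (event-free) to the horizon are
controls; non-converters censored before the horizon are excluded (they are
neither); a horizon at or beyond the longest follow-up reduces to the
any-time conversion outcome.

## Progression to symptomatic AD

`build_time_to_event` computes time from draw to onset (converters) or to
last follow-up (censored) for baseline-unimpaired participants, dropping and
counting nonpositive times. `fit_cox_per_protein` fits one proportional-
hazards model per analyte (standardized to SD 1, so hazard ratios are per SD
of log10 NPQ) adjusted for age and sex, with Efron tie handling — ties in
whole years are common with annual visits — and Breslow available.
`km_by_cutoff` compares Kaplan–Meier curves of cutoff-defined groups with a
two-sided log-rank test; covariate-adjusted curves, when requested, use
direct standardization (averaging Cox-predicted curves over the pooled
covariate distribution), with the unadjusted product-limit curves as the
primary output. Cox, Kaplan–Meier and log-rank computations use the survival
package; the test suite checks them against hand product-limit and
hypergeometric-increment computations on small fixtures.

## Technical reproducibility

`paired_correlations` computes per-analyte Pearson correlations between
paired runs (or platforms, via explicit sample pairings and analyte maps),
with pairwise-complete samples, flagging analytes with fewer than three
pairs. `iqr_vs_reproducibility` correlates each analyte's first-run IQR with
its cross-run correlation: under a constant technical noise model,
attenuation `r = s^2/(s^2 + t^2)` makes biologically variable analytes
reproduce better, so the correlation is expected positive.

## The synthetic cohort generator

`simulate_cohort` draws, on the log10 NPQ scale,

```
y[i, j] = b_j + beta[j, dx(i)] + a_j (age_i - mean age) + s_j male_i
          + sum_k lambda[j, k] f[i, k] + eps[i, j]
```

with two special analytes: the designated biomarker (`pTau217`) comes from a
two-component mixture conditioned on a latent positivity label whose
frequency differs by diagnosis, and the ε4 proteoform analyte (`APOE4`) is
baseline plus a carrier shift. Defaults emulate the structure of a large
memory-clinic cohort: group sizes 1,092 / 28 / 39 / 9 / 1,579 (AD / DLB /
FTD / PD / controls), 123 analytes, ages normal(74, 9) truncated to 45–100
(only cohort-level moments are ever published, so a common truncated normal
is used rather than per-group distributions), per-group male fractions and
a ~42% ε4 carrier rate typical of such referral cohorts, residual SD 0.15,
two standard-normal batch factors with loadings of SD 0.1, mixture
components (w1 = 0.52 via group positivity probabilities, modes 3.45 and
3.85 with SDs 0.12 and 0.18) placing the equal-posterior cutoff near log10
3.66, amyloid-PET available in ~10% of participants (positives linked to the
biomarker, negatives background noise around 5 Centiloids), 2% missingness
completely at random, and 0.5% injected outliers displaced 10 IQR beyond the
fences. Baseline log10 NPQ is a flat 2.5 — real panels have analyte-specific
baselines, but none are published, and every downstream analysis is
invariant to the baseline. The carrier shift of the proteoform analyte is
0.7 (≈4.7 residual SDs): the modes must be nearly disjoint for a
proteoform assay to agree with genotype at the ~99% level such assays
achieve; a two-SD shift would cap agreement near 84% (its Bayes error).

`simulate_survival` gives controls exponential conversion times with hazard
`0.012 * exp(log(1.71) * z)` per year (`z` the standardized biomarker),
censored administratively at a per-participant follow-up drawn uniformly
between 1 and 23 years — the spread of follow-up windows in long-running
cohorts — yielding roughly 9% converters.

Everything latent (true effects, positivity labels, batch factors and
loadings, carrier status, outlier and missing cells, clean values) is
returned in a truth record so that recovery tests never re-derive latents.
Identical configuration and seed give bitwise-identical cohorts; all
randomness is locally seeded and never touches the caller's RNG state.

What the generator does **not** emulate: plate/bridge structure and
intensity normalization (simulation starts at NPQ), analyte-specific
baselines and spreads, longitudinal within-participant trajectories,
non-Gaussian residuals, informative missingness, genotype–diagnosis
dependence (ε4 enrichment in AD is absent, so the proteoform analyte is not
disease-associated in simulation), and diagnostic misclassification.
Passing recovery tests on this generator therefore demonstrates correctness
of the estimators under the stated model, not robustness to every property
of real plasma data.

## Problem sizes and numerical conventions

The test suite exercises: mixture recovery at n = 10,000 (parameters within
±0.05); the equal-posterior root against a grid-plus-bisection oracle to
1e-6; Youden against brute force on 200 random instances; BH against an
independent step-up oracle on 1,000 random p-vectors; AUC within ±0.01 of
the closed-form binormal value Φ(Δμ/√(σ₀² + σ₁²)) at n = 10,000; β recovery
of a planted 0.26 group shift within ±0.02 of the mean over 50 seeds at
n = 1,000 + 1,500; Cox coverage of a planted hazard ratio 1.71 in ≥90% of
200 seeds at n = 950 with a 15-year horizon; and type-I error of the
association stage within [0.03, 0.07] on a null cohort of 1,000 analytes.
These sizes were chosen to make Monte-Carlo noise small relative to each
tolerance.

Numerical conventions collected in one place: type-7 quantiles everywhere;
EM tolerance 1e-8 relative with five quantile-split restarts and a 1e-6
variance floor; empirical (non-interpolated) thresholds for Youden and dual
cutoffs; integer-valued tie-breaking for Youden; concordance percentages
rounded half-up to two decimals; full-precision (`%.17g`) table
serialization so write→read→write is byte-identical; missing tokens `""`,
`NA`, `NaN`, `nan` on read, `NA` on write; matrices are samples-in-rows, and
a transposed file surfaces as an ID mismatch rather than a guess.
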