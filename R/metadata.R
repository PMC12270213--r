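#' Validate a sample-metadata table
#'
#' Checks a per-sample clinical/covariate table against the conventions the
#' pipeline assumes: one row per sample, diagnosis in {AD, DLB, FTD, PD, CO},
#' sex in {male, female}, APOE genotype from the six-value vocabulary (or
#' missing), and, where onset ages are present for baseline-unimpaired
#' converters, onset after draw.
#'
#' Expected columns (extra columns pass through untouched):
#' `sample_id`, `participant_id`, `age_at_draw`, `sex`, `diagnosis`,
#' `apoe_genotype`, `cdr`, `amyloid_pet` (Centiloids), `tau_pet` (SUVR),
#' `csf_ab_ratio`, `age_at_onset`, `age_at_last_followup`.
#'
#' @param meta A data.frame.
#' @return `meta`, invisibly, after validation.
#' @export
validate_metadata <- function(meta) {
  stopifnot(is.data.frame(meta))
  need <- c("sample_id", "participant_id", "age_at_draw", "sex", "diagnosis")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) stopf("metadata lacks column(s): %s",
                              paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) {
    stopf("duplicate sample_id: %s",
          meta$sample_id[duplicated(meta$sample_id)][1])
  }
  dx <- meta$diagnosis
  bad <- !is.na(dx) & !dx %in% c("AD", "DLB", "FTD", "PD", "CO")
  if (any(bad)) stopf("unknown diagnosis value(s): %s",
                      paste(unique(dx[bad]), collapse = ", "))
  male_indicator(meta$sex)
  if ("apoe_genotype" %in% names(meta)) {
    genotype_to_apoe4(meta$apoe_genotype) # errors on unknown strings
  }
  if ("age_at_onset" %in% names(meta)) {
    if (any(!is.na(meta$age_at_onset) & meta$age_at_onset < 0)) {
      stopf("age_at_onset must be non-negative")
    }
  }
  invisible(meta)
}

#' Read a sample-metadata table
#'
#' Reads a TSV/CSV metadata table (delimiter chosen by extension), coerces
#' the numeric clinical columns, and validates it with [validate_metadata()].
#'
#' @param path Path to a TSV/CSV file.
#' @return A validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  meta <- read_result_table(path)
  for (col in c("sample_id", "participant_id", "sex", "diagnosis",
                "apoe_genotype")) {
    if (col %in% names(meta)) meta[[col]] <- as.character(meta[[col]])
  }
  for (col in c("age_at_draw", "cdr", "amyloid_pet", "tau_pet",
                "csf_ab_ratio", "age_at_onset", "age_at_last_followup")) {
    if (col %in% names(meta)) meta[[col]] <- as.numeric(meta[[col]])
  }
  validate_metadata(meta)
  meta
}

#' Pipeline run configuration
#'
#' Bundles the tunable thresholds and model options shared by the pipeline
#' stages, with validity checks. Defaults are the study conventions: 65% /
#' 85% two-step call-rate thresholds, 1.5 x IQR outlier fences, 5% FDR,
#' amyloid positivity above 20 Centiloids, tau positivity above 1.5 SUVR,
#' CSF amyloid positivity below an Abeta42/Abeta40 ratio of 0.0673, two
#' surrogate variables, and a 2,000-replicate bootstrap for AUC intervals.
#'
#' @param seed Integer seed used by every randomized stage.
#' @param call_rate_step1,call_rate_step2 Call-rate thresholds in (0, 1],
#'   `call_rate_step1 <= call_rate_step2`.
#' @param iqr_k Positive IQR fence multiplier.
#' @param fdr_level Significance level on BH-adjusted p-values, in (0, 1).
#' @param amyloid_cutpoint Centiloid threshold for amyloid-PET positivity.
#' @param tau_cutpoint SUVR threshold for tau-PET positivity.
#' @param csf_cutpoint Abeta42/Abeta40 ratio below which CSF is
#'   amyloid-positive.
#' @param n_sv Number of surrogate variables.
#' @param em_tol,em_max_iter,em_restarts EM convergence tolerance, iteration
#'   cap, and number of quantile-split restarts for the mixture fit.
#' @param n_boot Bootstrap replicates for AUC confidence intervals.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       call_rate_step1 = 0.65, call_rate_step2 = 0.85,
                       iqr_k = 1.5, fdr_level = 0.05,
                       amyloid_cutpoint = 20, tau_cutpoint = 1.5,
                       csf_cutpoint = 0.0673,
                       n_sv = 2L, em_tol = 1e-8, em_max_iter = 1000L,
                       em_restarts = 5L, n_boot = 2000L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!(call_rate_step1 > 0 && call_rate_step1 <= 1 &&
        call_rate_step2 > 0 && call_rate_step2 <= 1)) {
    stopf("call-rate thresholds must lie in (0, 1]")
  }
  if (call_rate_step1 > call_rate_step2) {
    stopf("call_rate_step1 must not exceed call_rate_step2")
  }
  if (iqr_k <= 0) stopf("iqr_k must be positive")
  if (!(fdr_level > 0 && fdr_level < 1)) stopf("fdr_level must be in (0, 1)")
  structure(list(seed = as.integer(seed),
                 call_rate_step1 = call_rate_step1,
                 call_rate_step2 = call_rate_step2,
                 iqr_k = iqr_k, fdr_level = fdr_level,
                 amyloid_cutpoint = amyloid_cutpoint,
                 tau_cutpoint = tau_cutpoint, csf_cutpoint = csf_cutpoint,
                 n_sv = as.integer(n_sv), em_tol = em_tol,
                 em_max_iter = as.integer(em_max_iter),
                 em_restarts = as.integer(em_restarts),
                 n_boot = as.integer(n_boot)),
            class = "run_config")
}
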