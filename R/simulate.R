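#' Synthetic cohort configuration
#'
#' Parameters for [simulate_cohort()]. The defaults emulate the statistical
#' structure of a large mixed-dementia plasma-proteomics cohort: 123
#' analytes on a CNS panel measured in 2,747 participants (1,092 AD, 28 DLB,
#' 39 FTD, 9 PD, 1,579 cognitively unimpaired controls), a bimodal
#' p-tau217-like biomarker whose positivity fraction differs by diagnosis,
#' an amyloid-PET measure available in roughly 10% of participants and
#' linked to biomarker positivity, APOE genotypes with an epsilon-4
#' proteoform signal, latent batch structure, age/sex covariate effects,
#' completely-at-random missingness, injected outliers, and (via
#' [simulate_survival()]) conversion-to-AD event times for controls.
#'
#' All values are on the log10 NPQ scale unless noted. Per-analyte arguments
#' accept a scalar (recycled) or a vector of length `n_analytes`.
#'
#' @param n_per_group Named counts for groups AD, DLB, FTD, PD, CO.
#' @param n_analytes Number of analytes on the panel (>= 10; the first
#'   analytes are named `pTau217`, `GFAP`, `NEFL`, `pTau231`, `pTau181`,
#'   `NPTXR`, `BDNF`, `Abeta42`, `PARK7`, `APOE4`).
#' @param effect_matrix `n_analytes x 4` matrix of true group shifts (log10
#'   NPQ) for AD, DLB, FTD, PD vs control, or `NULL` for the default sparse
#'   pattern (a handful of disease-associated analytes with shifts of the
#'   magnitude seen on such panels, e.g. 0.16 for an astroglial marker in
#'   AD and -0.12 for a synaptic marker).
#' @param baseline Per-analyte baseline log10 NPQ (default 2.5; baselines
#'   are a repository convention, real panels do not share one).
#' @param age_effect Per-analyte slope per year of age (default 0.002).
#' @param sex_effect Per-analyte male-vs-female offset (default 0).
#' @param n_batch Number of latent standard-normal batch factors.
#' @param batch_loading_sd SD of the per-analyte loadings on each factor.
#' @param noise_sd Per-analyte residual SD (default 0.15).
#' @param biomarker_mix List `(w1, mu1, sigma1, mu2, sigma2)` for the
#'   biomarker mixture on the log10 scale; component 1 is the negative
#'   (lower) mode. `w1` is only used when `pos_prob` is `NULL`.
#' @param pos_prob Named per-group probabilities of latent biomarker
#'   positivity; set `NULL` to draw from the unconditional mixture.
#' @param pet_link List linking latent positivity to amyloid-PET Centiloids:
#'   positives get `intercept + slope * (biomarker - mu2) + N(0, noise_sd)`,
#'   negatives `N(background_mean, background_sd)`; `availability` is the
#'   fraction of participants with a PET value.
#' @param missing_rate Completely-at-random missingness rate in `[0, 1)`.
#' @param outlier_rate Fraction of observed cells displaced beyond the IQR
#'   fences, in `[0, 1)`.
#' @param outlier_mag Displacement magnitude in IQR multiples.
#' @param apoe_freqs Named frequencies of the six APOE genotypes.
#' @param apoe_shift Log10 shift of the epsilon-4 proteoform analyte in
#'   carriers. The default 0.7 (about 4.7 residual SDs) makes the
#'   carrier/non-carrier modes nearly disjoint, emulating the near-perfect
#'   genotype concordance of a proteoform-specific assay.
#' @param surv List with `baseline_hazard` (events per year for a control at
#'   the biomarker mean), `log_hr` (log hazard ratio per z-unit of the
#'   biomarker), `horizon` (maximum follow-up, years) and `min_followup`.
#' @param seed Integer seed; identical configurations give identical cohorts.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n_per_group = c(AD = 1092, DLB = 28, FTD = 39, PD = 9, CO = 1579),
    n_analytes = 123,
    effect_matrix = NULL,
    baseline = 2.5,
    age_effect = 0.002,
    sex_effect = 0,
    n_batch = 2,
    batch_loading_sd = 0.1,
    noise_sd = 0.15,
    biomarker_mix = list(w1 = 0.52, mu1 = 3.45, sigma1 = 0.12,
                         mu2 = 3.85, sigma2 = 0.18),
    pos_prob = c(AD = 0.85, DLB = 0.50, FTD = 0.35, PD = 0.35, CO = 0.30),
    pet_link = list(intercept = 60, slope = 80, noise_sd = 15,
                    background_mean = 5, background_sd = 8,
                    availability = 0.10),
    missing_rate = 0.02,
    outlier_rate = 0.005,
    outlier_mag = 10,
    apoe_freqs = c("e2/e2" = 0.005, "e2/e3" = 0.105, "e3/e3" = 0.470,
                   "e2/e4" = 0.025, "e3/e4" = 0.330, "e4/e4" = 0.065),
    apoe_shift = 0.7,
    surv = list(baseline_hazard = 0.012, log_hr = log(1.71),
                horizon = 23, min_followup = 1),
    seed = 1L) {
  groups <- c("AD", "DLB", "FTD", "PD", "CO")
  if (!all(groups %in% names(n_per_group))) {
    stopf("n_per_group must name all of %s", paste(groups, collapse = ", "))
  }
  n_per_group <- n_per_group[groups]
  if (any(n_per_group < 0)) stopf("group counts must be >= 0")
  if (n_analytes < 10) stopf("n_analytes must be >= 10")
  stopifnot(missing_rate >= 0, missing_rate < 1,
            outlier_rate >= 0, outlier_rate < 1)
  with(biomarker_mix, stopifnot(w1 > 0, w1 < 1, sigma1 > 0, sigma2 > 0))
  if (any(noise_sd <= 0)) stopf("noise_sd must be positive")
  if (abs(sum(apoe_freqs) - 1) > 1e-6) stopf("apoe_freqs must sum to 1")
  if (!is.null(pos_prob) && !all(groups %in% names(pos_prob))) {
    stopf("pos_prob must name all diagnosis groups")
  }
  expand <- function(x) {
    if (length(x) == 1) rep(x, n_analytes)
    else if (length(x) == n_analytes) x
    else stopf("per-analyte argument has length %d, expected 1 or %d",
               length(x), n_analytes)
  }
  cfg <- list(n_per_group = n_per_group, n_analytes = n_analytes,
              analyte_ids = default_analyte_ids(n_analytes),
              effect_matrix = effect_matrix,
              baseline = expand(baseline), age_effect = expand(age_effect),
              sex_effect = expand(sex_effect),
              n_batch = n_batch, batch_loading_sd = batch_loading_sd,
              noise_sd = expand(noise_sd),
              biomarker_mix = biomarker_mix, pos_prob = pos_prob,
              pet_link = pet_link, missing_rate = missing_rate,
              outlier_rate = outlier_rate, outlier_mag = outlier_mag,
              apoe_freqs = apoe_freqs, apoe_shift = apoe_shift,
              surv = surv, seed = as.integer(seed))
  if (is.null(cfg$effect_matrix)) {
    cfg$effect_matrix <- default_effects(cfg$analyte_ids)
  } else {
    stopifnot(nrow(cfg$effect_matrix) == n_analytes,
              ncol(cfg$effect_matrix) == 4)
    colnames(cfg$effect_matrix) <- c("AD", "DLB", "FTD", "PD")
    rownames(cfg$effect_matrix) <- cfg$analyte_ids
  }
  class(cfg) <- "cohort_sim_config"
  cfg
}

default_analyte_ids <- function(n) {
  named <- c("pTau217", "GFAP", "NEFL", "pTau231", "pTau181",
             "NPTXR", "BDNF", "Abeta42", "PARK7", "APOE4")
  c(named, sprintf("PROT%03d", seq_len(n - length(named)) + length(named)))
}

# Sparse default effect pattern with magnitudes typical of CNS panels:
# astroglial/axonal markers shifted up in several dementias, synaptic
# markers down in AD, a PD-specific oxidative-stress marker.
default_effects <- function(analyte_ids) {
  eff <- matrix(0, length(analyte_ids), 4,
                dimnames = list(analyte_ids, c("AD", "DLB", "FTD", "PD")))
  eff["GFAP", ]    <- c(0.16, 0.15, 0.12, 0)
  eff["NEFL", ]    <- c(0.09, 0.12, 0.27, 0)
  eff["pTau231", "AD"] <- 0.16
  eff["pTau181", "AD"] <- 0.09
  eff["NPTXR", "AD"]   <- -0.12
  eff["BDNF", "AD"]    <- -0.10
  eff["Abeta42", "AD"] <- -0.08
  eff["PARK7", c("AD", "PD")] <- c(-0.05, 0.34)
  eff
}

#' Simulate a synthetic plasma-proteomics cohort
#'
#' Draws a seeded cohort under the model
#' \deqn{y_{ij} = b_j + \beta_{j,dx(i)} + a_j (age_i - \bar{age}) +
#'       s_j \, male_i + \sum_k \lambda_{jk} f_{ik} + \epsilon_{ij}}
#' on the log10 NPQ scale, except for two special analytes: the designated
#' biomarker (`pTau217`), drawn from a two-component Gaussian mixture
#' conditioned on a latent positivity label, and the APOE epsilon-4
#' proteoform analyte (`APOE4`), drawn as baseline plus a carrier shift.
#' Amyloid-PET Centiloids are generated for a subsample, linked to the
#' biomarker for latent positives and to background noise for negatives;
#' tau-PET, CSF Abeta42/Abeta40 and CDR are drawn consistently with the
#' latent label. Outliers are injected beyond the 1.5 x IQR fences, then
#' missingness is applied completely at random.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A list with elements `matrix` (an [npq_matrix()], log10 scale),
#'   `meta` (a sample-metadata data.frame), and `truth` (every latent
#'   quantity: true effects, positivity labels, batch factors and loadings,
#'   APOE carrier status, injected outlier and missing cells, clean values).
#' @examples
#' cfg <- cohort_sim_config(n_per_group = c(AD = 30, DLB = 5, FTD = 5,
#'                                          PD = 5, CO = 30),
#'                          n_analytes = 12, seed = 7)
#' sim <- simulate_cohort(cfg)
#' dim(sim$matrix)
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  with_seed(cfg$seed, {
    groups <- names(cfg$n_per_group)
    dx <- rep(groups, times = cfg$n_per_group)
    n <- length(dx)
    if (n == 0) stopf("empty cohort: all group counts are zero")
    ids <- sprintf("S%05d", seq_len(n))
    pids <- sprintf("P%05d", seq_len(n))

    # Ages ~ N(74, 9) truncated to [45, 100]; sex frequencies per group
    # mirror a memory-clinic referral cohort.
    age <- stats::rnorm(n, 74, 9)
    while (any(bad <- age < 45 | age > 100)) {
      age[bad] <- stats::rnorm(sum(bad), 74, 9)
    }
    male_frac <- c(AD = 0.4368, DLB = 0.6429, FTD = 0.5641,
                   PD = 0.8889, CO = 0.4022)
    sex <- unname(ifelse(stats::runif(n) < male_frac[dx], "male", "female"))

    # Latent biomarker positivity and mixture draw.
    mix <- cfg$biomarker_mix
    p_pos <- if (is.null(cfg$pos_prob)) rep(1 - mix$w1, n) else cfg$pos_prob[dx]
    positive <- unname(stats::runif(n) < p_pos)
    biomarker <- ifelse(positive,
                        stats::rnorm(n, mix$mu2, mix$sigma2),
                        stats::rnorm(n, mix$mu1, mix$sigma1))

    # APOE genotype and epsilon-4 carrier status.
    genotype <- sample(names(cfg$apoe_freqs), n, replace = TRUE,
                       prob = cfg$apoe_freqs)
    carrier <- genotype_to_apoe4(genotype)

    # Batch structure and residual noise for the modelled analytes.
    p <- cfg$n_analytes
    aids <- cfg$analyte_ids
    loadings <- matrix(stats::rnorm(p * cfg$n_batch, 0, cfg$batch_loading_sd),
                       p, cfg$n_batch, dimnames = list(aids, NULL))
    factors <- matrix(stats::rnorm(n * cfg$n_batch), n, cfg$n_batch,
                      dimnames = list(ids, NULL))
    eff <- cbind(cfg$effect_matrix, CO = 0)
    values <- matrix(NA_real_, n, p, dimnames = list(ids, aids))
    age_c <- age - mean(age)
    male <- as.integer(sex == "male")
    for (j in seq_len(p)) {
      values[, j] <- cfg$baseline[j] + eff[j, dx] +
        cfg$age_effect[j] * age_c + cfg$sex_effect[j] * male +
        factors %*% loadings[j, ] +
        stats::rnorm(n, 0, cfg$noise_sd[j])
    }
    values[, "pTau217"] <- biomarker
    values[, "APOE4"] <- cfg$baseline[match("APOE4", aids)] +
      cfg$apoe_shift * carrier +
      stats::rnorm(n, 0, cfg$noise_sd[match("APOE4", aids)])
    clean <- values

    # Endophenotypes tied to the latent positivity label.
    pl <- cfg$pet_link
    pet_avail <- stats::runif(n) < pl$availability
    amyloid <- ifelse(positive,
                      pl$intercept + pl$slope * (biomarker - mix$mu2) +
                        stats::rnorm(n, 0, pl$noise_sd),
                      stats::rnorm(n, pl$background_mean, pl$background_sd))
    amyloid[!pet_avail] <- NA_real_
    tau_avail <- stats::runif(n) < pl$availability
    tau <- ifelse(positive, stats::rnorm(n, 1.9, 0.35),
                  stats::rnorm(n, 1.2, 0.15))
    tau[!tau_avail] <- NA_real_
    csf_avail <- stats::runif(n) < 0.18
    csf <- ifelse(positive, stats::rnorm(n, 0.055, 0.008),
                  stats::rnorm(n, 0.085, 0.010))
    csf[!csf_avail] <- NA_real_
    cdr <- ifelse(dx == "CO", 0,
                  sample(c(0.5, 1, 2), n, replace = TRUE,
                         prob = c(0.5, 0.35, 0.15)))
    cdr[stats::runif(n) > 0.9] <- NA_real_

    # Inject outliers beyond the k = 1.5 fences, then MCAR missingness.
    outlier_cells <- NULL
    if (cfg$outlier_rate > 0) {
      n_out <- round(cfg$outlier_rate * n * p)
      cell <- sample.int(n * p, n_out)
      rows <- (cell - 1) %% n + 1
      cols <- (cell - 1) %/% n + 1
      up <- stats::runif(n_out) < 0.5
      for (k in seq_len(n_out)) {
        x <- clean[, cols[k]]
        q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
        iqr <- q[2] - q[1]
        values[rows[k], cols[k]] <- if (up[k]) q[2] + cfg$outlier_mag * iqr
                                    else q[1] - cfg$outlier_mag * iqr
      }
      outlier_cells <- cbind(row = rows, col = cols)
    }
    missing_cells <- NULL
    if (cfg$missing_rate > 0) {
      n_miss <- round(cfg$missing_rate * n * p)
      cell <- sample.int(n * p, n_miss)
      rows <- (cell - 1) %% n + 1
      cols <- (cell - 1) %/% n + 1
      values[cbind(rows, cols)] <- NA_real_
      missing_cells <- cbind(row = rows, col = cols)
    }

    meta <- data.frame(
      sample_id = ids, participant_id = pids,
      age_at_draw = age, sex = sex, diagnosis = dx,
      apoe_genotype = genotype, cdr = cdr,
      amyloid_pet = amyloid, tau_pet = tau, csf_ab_ratio = csf,
      age_at_onset = ifelse(dx == "CO", NA_real_,
                            pmax(age - stats::rexp(n, 1 / 4), 45)),
      age_at_last_followup = age + stats::runif(n, 0.5, 5),
      stringsAsFactors = FALSE
    )
    truth <- list(effect_matrix = cfg$effect_matrix, positive = positive,
                  biomarker = biomarker, batch_factors = factors,
                  batch_loadings = loadings, apoe_carrier = carrier,
                  outlier_cells = outlier_cells,
                  missing_cells = missing_cells, clean_values = clean,
                  age = age, male = male)
    list(matrix = npq_matrix(values, scale = "log10"), meta = meta,
         truth = truth)
  })
}

#' Simulate progression-to-AD event times for controls
#'
#' For baseline cognitively-unimpaired participants, draws exponential
#' conversion times with hazard
#' `baseline_hazard * exp(log_hr * z)` where `z` is the cohort-standardized
#' biomarker, applies administrative censoring at a per-participant
#' follow-up drawn uniformly between `min_followup` and `horizon` years, and
#' fills `age_at_onset` (converters) or `age_at_last_followup` (censored)
#' accordingly.
#'
#' @param meta Metadata from [simulate_cohort()].
#' @param truth Truth record from [simulate_cohort()] (supplies the latent
#'   biomarker values).
#' @param cfg The same [cohort_sim_config()]; its `surv` element is used.
#' @return `meta` with follow-up columns filled for controls and a logical
#'   column `converted_to_ad`; converters keep diagnosis `CO` (their status
#'   at draw). The realized event times are recorded in
#'   `attr(, "event_times")`.
#' @export
simulate_survival <- function(meta, truth, cfg) {
  sv <- cfg$surv
  if (sv$baseline_hazard <= 0) stopf("baseline_hazard must be positive")
  if (sv$horizon <= 0) stopf("infeasible follow-up horizon: %g", sv$horizon)
  is_co <- meta$diagnosis == "CO"
  if (!any(is_co)) stopf("no control participants: survival simulation infeasible")
  with_seed(cfg$seed + 1L, {
    z <- (truth$biomarker - mean(truth$biomarker)) / stats::sd(truth$biomarker)
    n_co <- sum(is_co)
    rate <- sv$baseline_hazard * exp(sv$log_hr * z[is_co])
    t_event <- stats::rexp(n_co, rate)
    t_cens <- stats::runif(n_co, sv$min_followup, sv$horizon)
    event <- t_event <= t_cens
    time <- pmin(t_event, t_cens)
    meta$converted_to_ad <- NA
    meta$converted_to_ad[is_co] <- event
    meta$age_at_onset[is_co] <- ifelse(event, meta$age_at_draw[is_co] + time,
                                       NA_real_)
    meta$age_at_last_followup[is_co] <- meta$age_at_draw[is_co] + time
    attr(meta, "event_times") <- data.frame(
      sample_id = meta$sample_id[is_co], time = time, event = event)
    meta
  })
}
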