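co_meta <- function() {
  data.frame(
    sample_id = paste0("S", 1:6), participant_id = paste0("P", 1:6),
    age_at_draw = c(70, 70, 68, 75, 72, 71),
    sex = rep(c("male", "female"), 3),
    diagnosis = "CO",
    age_at_onset = c(75, NA, 70, NA, 73, NA),
    age_at_last_followup = c(75, 93, 70, 77, 73, 74),
    converted_to_ad = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
}

test_that("time-to-event construction follows draw/onset/follow-up ages", {
  meta <- co_meta()
  tte <- build_time_to_event(meta)
  expect_equal(tte$time[tte$sample_id == "S1"], 5)
  expect_true(tte$event[tte$sample_id == "S1"])
  expect_equal(tte$time[tte$sample_id == "S2"], 23)
  expect_false(tte$event[tte$sample_id == "S2"])

  # onset before draw -> dropped and counted
  meta$age_at_onset[3] <- 60
  tte2 <- build_time_to_event(meta)
  expect_false("S3" %in% tte2$sample_id)
  expect_equal(attr(tte2, "n_dropped"), 1)

  # non-CO participants never enter
  meta$diagnosis[4] <- "AD"
  expect_false("S4" %in% build_time_to_event(meta)$sample_id)
})

test_that("Kaplan-Meier estimator matches the hand product-limit fixture", {
  time <- c(1, 2, 2, 4, 5, 7)
  event <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  hand <- km_oracle(time, event)
  got <- summary(sf, times = hand$time)$surv
  expect_equal(got, hand$surv)
  # survival is 1 before the first event in both groups of a comparison
  expect_equal(summary(sf, times = 0)$surv, 1)
})

test_that("log-rank test matches the hypergeometric-increment oracle", {
  set.seed(501)
  for (i in 1:5) {
    n <- 40
    time <- ceiling(rexp(n, 0.2))       # ties guaranteed
    event <- runif(n) < 0.7
    group <- rep(c("a", "b"), each = n / 2)
    tte <- data.frame(participant_id = seq_len(n), sample_id = seq_len(n),
                      time = time, event = event)
    km <- km_by_cutoff(tte, group)
    expect_equal(km$logrank_chisq, logrank_oracle(time, event, group),
                 tolerance = 1e-10)
  }
})

test_that("km_by_cutoff validates groups and supports adjusted curves", {
  meta <- co_meta()
  tte <- build_time_to_event(meta)
  expect_error(km_by_cutoff(tte, rep("high", nrow(tte))), "non-empty")
  expect_error(km_by_cutoff(tte[tte$event == FALSE, ],
                            c("a", "b", "a")), "events")
  set.seed(503)
  n <- 150
  tte2 <- data.frame(participant_id = sprintf("P%03d", 1:n),
                     sample_id = sprintf("S%03d", 1:n),
                     time = rexp(n, 0.1), event = runif(n) < 0.6)
  grp <- rep(c("high", "low"), length.out = n)
  km <- km_by_cutoff(tte2, grp, covariates = data.frame(
    age = runif(n, 65, 85), male = rep(0:1, length.out = n)))
  expect_s3_class(km, "km_comparison")
  expect_true(!is.null(km$adjusted))
  expect_true(all(km$adjusted$surv >= 0 & km$adjusted$surv <= 1))
  expect_setequal(unique(km$adjusted$group), c("high", "low"))
})

test_that("per-protein Cox fits recover planted hazard ratios", {
  res <- vapply(1:15, function(s) {
    cfg <- cohort_sim_config(
      n_per_group = c(AD = 0, DLB = 0, FTD = 0, PD = 0, CO = 950),
      n_analytes = 12, missing_rate = 0, outlier_rate = 0,
      surv = list(baseline_hazard = 0.012, log_hr = log(1.71),
                  horizon = 15, min_followup = 1),
      seed = 900 + s)
    sim <- simulate_cohort(cfg)
    meta <- simulate_survival(sim$meta, sim$truth, cfg)
    tte <- build_time_to_event(meta)
    tab <- fit_cox_per_protein(tte, sim$matrix, meta)
    rec <- tab[tab$analyte_id == "pTau217", ]
    c(hr = rec$hr, covered = rec$ci_lower <= 1.71 && 1.71 <= rec$ci_upper)
  }, numeric(2))
  expect_lt(abs(mean(res["hr", ]) - 1.71), 0.15)
  expect_gte(mean(res["covered", ]), 0.9)
})

test_that("null analytes cover HR = 1 and zero-variance analytes are flagged", {
  cfg <- cohort_sim_config(
    n_per_group = c(AD = 0, DLB = 0, FTD = 0, PD = 0, CO = 500),
    n_analytes = 20, missing_rate = 0, outlier_rate = 0,
    batch_loading_sd = 0,
    surv = list(baseline_hazard = 0.03, log_hr = log(1.71),
                horizon = 15, min_followup = 1),
    seed = 55)
  sim <- simulate_cohort(cfg)
  meta <- simulate_survival(sim$meta, sim$truth, cfg)
  tte <- build_time_to_event(meta)
  tab <- fit_cox_per_protein(tte, sim$matrix, meta)
  # analytes carrying no survival signal (everything except the biomarker
  # and correlates of it) should mostly cover 1
  null_rows <- !tab$analyte_id %in% c("pTau217")
  cover <- tab$ci_lower[null_rows] <= 1 & 1 <= tab$ci_upper[null_rows]
  expect_gte(mean(cover), 0.8)
  expect_true(all(tab$hr > 0, na.rm = TRUE))
  expect_true(all(tab$ci_lower <= tab$hr & tab$hr <= tab$ci_upper,
                  na.rm = TRUE))

  v <- unclass(sim$matrix)
  v[, 5] <- 3 # constant analyte
  tab2 <- fit_cox_per_protein(tte, npq_matrix(v, "log10"), meta)
  expect_identical(tab2$flag[5], "degenerate")
})

test_that("protective effects are recovered with the right sign", {
  signs <- vapply(1:10, function(s) {
    cfg <- cohort_sim_config(
      n_per_group = c(AD = 0, DLB = 0, FTD = 0, PD = 0, CO = 600),
      n_analytes = 12, missing_rate = 0, outlier_rate = 0,
      surv = list(baseline_hazard = 0.03, log_hr = log(0.44),
                  horizon = 15, min_followup = 1),
      seed = 950 + s)
    sim <- simulate_cohort(cfg)
    meta <- simulate_survival(sim$meta, sim$truth, cfg)
    tte <- build_time_to_event(meta)
    tab <- fit_cox_per_protein(tte, sim$matrix, meta)
    tab$hr[tab$analyte_id == "pTau217"] < 1
  }, logical(1))
  expect_gte(mean(signs), 0.95)
})

test_that("single-sex cohorts fit cleanly (zero-variance covariate)", {
  set.seed(502)
  n <- 120
  meta <- data.frame(sample_id = sprintf("S%03d", 1:n),
                     participant_id = sprintf("P%03d", 1:n),
                     age_at_draw = runif(n, 65, 85),
                     sex = "male", diagnosis = "CO")
  tte <- data.frame(participant_id = meta$participant_id,
                    sample_id = meta$sample_id,
                    time = rexp(n, 0.1), event = runif(n) < 0.6)
  v <- matrix(rnorm(n * 3, 3, 0.2), n, 3,
              dimnames = list(meta$sample_id, c("A", "B", "C")))
  tab <- fit_cox_per_protein(tte, npq_matrix(v, "log10"), meta)
  expect_identical(tab$flag, rep("ok", 3))
  # hazard ratio per SD equals a direct age-only adjusted fit
  d <- data.frame(time = tte$time, event = tte$event,
                  z = as.numeric(scale(v[, 1])), age = meta$age_at_draw)
  direct <- survival::coxph(survival::Surv(time, event) ~ z + age, data = d)
  expect_equal(tab$hr[1], unname(exp(coef(direct)["z"])), tolerance = 1e-8)
})
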