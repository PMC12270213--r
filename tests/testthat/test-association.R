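test_that("surrogate variables recover planted batch factors", {
  cfg <- cohort_sim_config(
    n_per_group = c(AD = 150, DLB = 0, FTD = 0, PD = 0, CO = 250),
    n_analytes = 100, n_batch = 2, batch_loading_sd = 0.3,
    missing_rate = 0, outlier_rate = 0, seed = 41)
  sim <- simulate_cohort(cfg)
  svs <- estimate_surrogate_variables(sim$matrix, sim$meta, n_sv = 2)
  cc <- stats::cancor(as.matrix(svs[, c("sv1", "sv2")]),
                      sim$truth$batch_factors)$cor
  expect_gte(min(cc), 0.9)
  # mean zero and mutual orthogonality
  expect_lt(max(abs(colMeans(svs[, -1]))), 1e-8)
  expect_lt(abs(sum(svs$sv1 * svs$sv2)), 1e-8)
})

test_that("surrogate-variable imputation is seed-deterministic", {
  cfg <- small_cfg(seed = 42, missing_rate = 0.1)
  sim <- simulate_cohort(cfg)
  s1 <- estimate_surrogate_variables(sim$matrix, sim$meta, seed = 3)
  s2 <- estimate_surrogate_variables(sim$matrix, sim$meta, seed = 3)
  expect_identical(s1, s2)
  expect_error(estimate_surrogate_variables(sim$matrix, sim$meta, n_sv = 12),
               "smaller than")
})

test_that("with no batch structure, SV adjustment barely moves betas", {
  diffs <- vapply(1:10, function(s) {
    cfg <- cohort_sim_config(
      n_per_group = c(AD = 100, DLB = 0, FTD = 0, PD = 0, CO = 100),
      n_analytes = 30, batch_loading_sd = 0, missing_rate = 0,
      outlier_rate = 0, seed = 500 + s)
    sim <- simulate_cohort(cfg)
    svs <- estimate_surrogate_variables(sim$matrix, sim$meta)
    with_sv <- fit_associations(sim$matrix, sim$meta, "AD_vs_CO", svs = svs)
    without <- fit_associations(sim$matrix, sim$meta, "AD_vs_CO")
    mean(abs(with_sv$beta - without$beta) / without$se, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(diffs), 0.5)
})

test_that("all-zero surrogate variables reproduce the unadjusted fit", {
  cfg <- small_cfg(seed = 43)
  sim <- simulate_cohort(cfg)
  zero_svs <- data.frame(sample_id = sim$meta$sample_id, sv1 = 0, sv2 = 0)
  a <- fit_associations(sim$matrix, sim$meta, "AD_vs_CO", svs = zero_svs)
  b <- fit_associations(sim$matrix, sim$meta, "AD_vs_CO")
  expect_equal(a$beta, b$beta, tolerance = 1e-10)
  expect_equal(a$se, b$se, tolerance = 1e-10)
})

test_that("disease and phenotype contrasts use the specified samples", {
  cfg <- small_cfg(seed = 44)
  sim <- simulate_cohort(cfg)
  ad <- fit_associations(sim$matrix, sim$meta, "AD_vs_CO")
  expect_true(all(ad$n_used <= sum(sim$meta$diagnosis %in% c("AD", "CO"))))
  expect_warning(fit_associations(sim$matrix, sim$meta, "PD_vs_CO"),
                 "only .* cases")
  amy <- suppressMessages(
    fit_associations(sim$matrix, sim$meta, "amyloid_pet"))
  expect_true(all(amy$n_used <= sum(!is.na(sim$meta$amyloid_pet))))
  expect_error(fit_associations(sim$matrix, sim$meta, "bogus"),
               "unknown contrast")
})

test_that("constant analytes yield a flagged record with missing p", {
  v <- matrix(rnorm(200, 3), 20, 10,
              dimnames = list(sprintf("S%02d", 1:20), sprintf("A%02d", 1:10)))
  v[, 4] <- 2.5
  m <- npq_matrix(v, "log10")
  meta <- data.frame(sample_id = rownames(v),
                     participant_id = rownames(v),
                     age_at_draw = runif(20, 60, 90),
                     sex = rep(c("male", "female"), 10),
                     diagnosis = rep(c("AD", "CO"), each = 10))
  tab <- fit_associations(m, meta, "AD_vs_CO")
  rec <- tab[tab$analyte_id == "A04", ]
  expect_equal(rec$beta, 0)
  expect_true(is.na(rec$p_raw))
  expect_identical(rec$flag, "degenerate")
  expect_identical(tab$flag[tab$analyte_id != "A04"], rep("ok", 9))
})

test_that("BH adjustment equals the step-up oracle and is order-invariant", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.5), 0.5)
  expect_error(adjust_fdr(c(0.5, 0)), "0, 1")
  set.seed(99)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(adjust_fdr(p), bh_oracle(p))
  }
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_fdr(p)[perm], adjust_fdr(p[perm]))
  expect_true(all(adjust_fdr(p) >= p))
})

test_that("self-comparison of effect sizes gives r = 1 and no outliers", {
  pair <- make_effect_pair(seed = 1, n_discordant = 0)
  cmp <- compare_effect_sizes(pair$a, pair$a)
  expect_equal(cmp$r, 1)
  expect_equal(nrow(cmp$band_outliers), 0)
  expect_length(cmp$discordant_sign, 0)
})

test_that("planted discordant analytes are flagged by the 95% band", {
  for (s in 1:5) {
    pair <- make_effect_pair(seed = s, n_discordant = 3)
    cmp <- compare_effect_sizes(pair$a, pair$b)
    expect_true(all(pair$planted %in% cmp$band_outliers$analyte_id))
    expect_true(all(pair$planted %in% cmp$discordant_sign))
  }
})

test_that("effect comparison r is symmetric; few shared analytes error", {
  pair <- make_effect_pair(seed = 2)
  ab <- compare_effect_sizes(pair$a, pair$b)
  ba <- compare_effect_sizes(pair$b, pair$a)
  expect_equal(ab$r, ba$r)
  expect_error(compare_effect_sizes(pair$a[1:2, ], pair$b[1:2, ]),
               "fewer than 3")
})
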