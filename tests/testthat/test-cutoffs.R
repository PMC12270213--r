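test_that("EM recovers well-separated mixture parameters at n = 10,000", {
  set.seed(202)
  x <- c(rnorm(5000, -1, 0.5), rnorm(5000, 1, 0.5))
  fit <- fit_two_component_gmm(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$w1 - 0.5), 0.05)
  expect_lt(abs(fit$mu1 - (-1)), 0.05)
  expect_lt(abs(fit$mu2 - 1), 0.05)
  expect_lt(abs(fit$sigma1 - 0.5), 0.05)
  expect_lt(abs(fit$sigma2 - 0.5), 0.05)
  expect_false(fit$low_confidence)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  set.seed(203)
  for (s in 1:5) {
    x <- c(rnorm(300, -1, 0.4 + 0.1 * s), rnorm(200 + 50 * s, 1, 0.6))
    fit <- fit_two_component_gmm(x)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("EM agrees with an established mixture fitter on a fixture", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust)) # Mclust needs attachment
  set.seed(204)
  x <- c(rnorm(800, -0.9, 0.45), rnorm(1200, 0.8, 0.7))
  fit <- fit_two_component_gmm(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$mu1, min(mc$parameters$mean), tolerance = 0.02)
  expect_equal(fit$mu2, max(mc$parameters$mean), tolerance = 0.02)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-4)
})

test_that("degenerate unimodal input converges with a low-confidence flag", {
  set.seed(205)
  x <- rnorm(2000)
  fit <- fit_two_component_gmm(x)
  expect_true(fit$converged)
  expect_true(fit$low_confidence)
  expect_error(fit_two_component_gmm(rnorm(10)), "at least 20")
  expect_error(fit_two_component_gmm(rep(1, 30)), "zero variance")
})

test_that("equal-posterior cutoff solves the posterior balance equation", {
  sym <- list(w1 = 0.5, w2 = 0.5, mu1 = -1, mu2 = 1, sigma1 = 1, sigma2 = 1)
  expect_equal(equal_posterior_cutoff(sym), 0, tolerance = 1e-12)

  cases <- list(
    list(w1 = 0.3, w2 = 0.7, mu1 = -1, mu2 = 1, sigma1 = 0.5, sigma2 = 0.8),
    list(w1 = 0.6, w2 = 0.4, mu1 = 0, mu2 = 2, sigma1 = 0.3, sigma2 = 0.3),
    list(w1 = 0.52, w2 = 0.48, mu1 = -0.9, mu2 = 0.95,
         sigma1 = 0.45, sigma2 = 0.75))
  for (p in cases) {
    z <- equal_posterior_cutoff(p)
    oracle <- equal_posterior_oracle(p$w1, p$mu1, p$sigma1,
                                     p$w2, p$mu2, p$sigma2)
    expect_equal(z, oracle, tolerance = 1e-6)
    # posterior membership probabilities are equal at the cutoff
    post1 <- p$w1 * dnorm(z, p$mu1, p$sigma1)
    post2 <- p$w2 * dnorm(z, p$mu2, p$sigma2)
    expect_lt(abs(post1 / (post1 + post2) - 0.5), 1e-6)
  }
})

test_that("gmm_cutoff expresses the cutoff consistently on all scales", {
  set.seed(206)
  x <- c(rnorm(900, 3.45, 0.12), rnorm(800, 3.85, 0.18))
  mod <- gmm_cutoff(x)
  expect_gt(mod$z_cutoff, mod$mu1)
  expect_lt(mod$z_cutoff, mod$mu2)
  std <- mod$standardization
  expect_equal(mod$cutoff_log10, std["mean"] + std["sd"] * mod$z_cutoff,
               ignore_attr = TRUE)
  expect_equal(mod$cutoff_linear, 10^mod$cutoff_log10)
  # the cutoff lands between the component modes on the data scale
  expect_gt(mod$cutoff_log10, 3.45)
  expect_lt(mod$cutoff_log10, 3.85)
})

test_that("GMM and Youden cutoffs agree on well-separated mixtures", {
  set.seed(207)
  lab <- rep(c(FALSE, TRUE), each = 5000)
  x <- c(rnorm(5000, -1, 0.5), rnorm(5000, 1, 0.5))
  fit <- fit_two_component_gmm(x)
  gmm_cut <- equal_posterior_cutoff(fit)
  yj <- youden_cutoff(x, lab)
  expect_lt(abs(gmm_cut - yj$threshold), 0.1)
})

test_that("Youden cutoff equals the brute-force maximizer", {
  y <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(y$threshold, 0.8)
  expect_equal(y$youden_j, 1)

  set.seed(208)
  for (i in 1:200) {
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), sample(0:2, 1)) # ties likely
    labels <- runif(n) < 0.4
    if (length(unique(labels)) < 2) next
    got <- youden_cutoff(scores, labels)
    want <- youden_oracle(scores, labels)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$youden_j, want$youden_j)
  }
  expect_error(youden_cutoff(1:5, rep(1, 5)), "both classes")
  deg <- youden_cutoff(rep(1, 10), rep(c(0, 1), 5))
  expect_true(deg$degenerate)
  expect_equal(deg$youden_j, 0)
})

test_that("dual cutoffs hit their sensitivity/specificity targets", {
  for (s in 1:10) {
    set.seed(400 + s)
    lab <- rep(c(FALSE, TRUE), each = 1000)
    x <- c(rnorm(1000, 0, 1), rnorm(1000, 2, 1))
    dc <- dual_cutoffs(x, lab)
    expect_gte(dc$sensitivity_at_lower, 0.95)
    expect_gte(dc$specificity_at_upper, 0.95)
    expect_lte(dc$lower, dc$upper)
    expect_equal(sum(dc$counts), 2000)
    # class assignment is monotone in score
    cls <- as.integer(dc$class)
    expect_true(all(diff(cls[order(x)]) >= 0))
  }
})

test_that("perfect separation collapses the intermediate zone", {
  suppressMessages({
    dc <- dual_cutoffs(c(1:10, 101:110), rep(c(FALSE, TRUE), each = 10))
  })
  expect_equal(dc$counts[["intermediate"]],
               sum(c(1:10, 101:110) >= dc$lower & c(1:10, 101:110) <= dc$upper))
  expect_gte(dc$sensitivity_at_lower, 0.95)
  expect_gte(dc$specificity_at_upper, 0.95)
  # low class entirely negative, high class entirely positive
  cm <- confusion(dc$class, rep(c(FALSE, TRUE), each = 10),
                  drop_intermediate = TRUE)
  expect_equal(cm$fp + cm$fn, 0)
})

test_that("PET and CSF reference rules respect boundaries", {
  meta <- data.frame(sample_id = paste0("S", 1:5),
                     amyloid_pet = c(21, 19, 20, NA, 60),
                     tau_pet = c(1.6, 1.4, 1.5, NA, 2.0),
                     csf_ab_ratio = c(0.05, 0.08, 0.0673, NA, 0.02))
  expect_identical(unname(pet_reference(meta, "amyloid")),
                   c(TRUE, FALSE, FALSE, NA, TRUE))
  expect_identical(unname(pet_reference(meta, "tau")),
                   c(TRUE, FALSE, FALSE, NA, TRUE))
  expect_identical(unname(pet_reference(meta, "csf")),
                   c(TRUE, FALSE, FALSE, NA, TRUE))
})
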