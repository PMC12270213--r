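# Independent oracles and small fixtures shared across the suite.
# Oracles are deliberately naive re-derivations (loops, closed forms,
# bisection) that never call the implementation they check.

small_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_per_group = c(AD = 60, DLB = 10, FTD = 10, PD = 5, CO = 60),
         n_analytes = 12, missing_rate = 0.01, outlier_rate = 0,
         seed = seed),
    list(...))
  do.call(cohort_sim_config, args)
}

# Benjamini-Hochberg step-up, coded directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, m * p[ord[i]] / i)
    adj[ord[i]] <- running_min
  }
  pmin(adj, 1)
}

# Exhaustive Youden maximizer: counts every confusion cell per candidate.
youden_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(scores))
  best_t <- NA_real_
  best_j <- -Inf
  for (t in cand) {
    tp <- sum(scores >= t & labels)
    fn <- sum(scores < t & labels)
    tn <- sum(scores < t & !labels)
    fp <- sum(scores >= t & !labels)
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, youden_j = best_j)
}

# Grid + bisection root of w1 phi1(z) = w2 phi2(z) on (mu1, mu2).
equal_posterior_oracle <- function(w1, mu1, s1, w2, mu2, s2, tol = 1e-10) {
  f <- function(z) w1 * dnorm(z, mu1, s1) - w2 * dnorm(z, mu2, s2)
  grid <- seq(mu1 + 1e-9, mu2 - 1e-9, length.out = 2001)
  fg <- f(grid)
  k <- which(fg[-1] * fg[-length(fg)] <= 0)[1]
  if (is.na(k)) stop("oracle: no sign change")
  lo <- grid[k]; hi <- grid[k + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Hand product-limit estimator: returns survival after each distinct
# event time.
km_oracle <- function(time, event) {
  tt <- sort(unique(time[event]))
  s <- 1
  out <- data.frame(time = tt, surv = NA_real_)
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Two-group log-rank statistic from hypergeometric increments.
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1
  tt <- sort(unique(time[event]))
  o_minus_e <- 0
  v <- 0
  for (t in tt) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Association tables with a shared effect profile plus planted
# discordant analytes, for the effect-size comparison tests.
make_effect_pair <- function(seed, n_analytes = 100, n_discordant = 3,
                             resid_sd = 0.03) {
  set.seed(seed)
  beta_a <- rnorm(n_analytes, 0, 0.2)
  beta_b <- beta_a + rnorm(n_analytes, 0, resid_sd)
  planted <- order(-abs(beta_a))[seq_len(n_discordant)]
  beta_b[planted] <- -beta_a[planted]
  ids <- sprintf("A%03d", seq_len(n_analytes))
  mk <- function(beta, contrast) {
    data.frame(analyte_id = ids, contrast = contrast, beta = beta,
               se = resid_sd, p_raw = 1e-4, p_fdr = 1e-3,
               n_used = 100L, flag = "ok", stringsAsFactors = FALSE)
  }
  list(a = mk(beta_a, "AD_vs_CO"), b = mk(beta_b, "DLB_vs_CO"),
       planted = ids[planted])
}
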