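#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Expectation-maximization for `w1 N(mu1, sigma1^2) + w2 N(mu2, sigma2^2)`
#' with unequal variances. Restart `r` (r = 0, 1, ...) initializes by
#' splitting the data at its `0.3 + 0.1 r` quantile and taking component
#' weights and moments from each side; the best converged log-likelihood is
#' kept. A variance floor of `1e-6` guards against component collapse.
#' Components are relabelled so `mu1 < mu2`.
#'
#' @param x Numeric vector (at least 20 finite values with positive SD);
#'   typically z-scored log10 biomarker values.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap per restart.
#' @param restarts Number of quantile-split initializations.
#' @return A list of class `gmm_fit`: `w1`, `w2`, `mu1`, `mu2`, `sigma1`,
#'   `sigma2`, `loglik`, `n_iter`, `converged`, `loglik_trace` (of the best
#'   restart), and `low_confidence` (`TRUE` when the modes are closer than
#'   `sigma1 + sigma2`, i.e. the data look unimodal).
#' @export
fit_two_component_gmm <- function(x, tol = 1e-8, max_iter = 1000,
                                  restarts = 5) {
  x <- x[is.finite(x)]
  if (length(x) < 20) stopf("need at least 20 finite values, got %d", length(x))
  if (stats::sd(x) == 0) stopf("input has zero variance")
  var_floor <- 1e-6
  best <- NULL
  for (r in seq_len(restarts) - 1L) {
    q <- stats::quantile(x, 0.3 + 0.1 * r, type = 7, names = FALSE)
    left <- x[x <= q]
    right <- x[x > q]
    if (length(left) < 2 || length(right) < 2) next
    par <- list(w1 = length(left) / length(x),
                mu1 = mean(left), mu2 = mean(right),
                s1 = max(stats::sd(left), sqrt(var_floor)),
                s2 = max(stats::sd(right), sqrt(var_floor)))
    fit <- em_univariate(x, par, tol, max_iter, var_floor)
    if (is.null(best) ||
        (fit$converged && !best$converged) ||
        (fit$converged == best$converged && fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  if (is.null(best)) stopf("no valid initialization (degenerate input)")
  if (!best$converged) {
    cond <- simpleError(sprintf(
      "EM did not converge in %d iterations in any of %d restarts", max_iter,
      restarts))
    cond$partial_fit <- best
    stop(cond)
  }
  if (best$mu1 > best$mu2) {
    best[c("w1", "w2")] <- best[c("w2", "w1")]
    best[c("mu1", "mu2")] <- best[c("mu2", "mu1")]
    best[c("sigma1", "sigma2")] <- best[c("sigma2", "sigma1")]
  }
  best$low_confidence <- (best$mu2 - best$mu1) < (best$sigma1 + best$sigma2)
  class(best) <- "gmm_fit"
  best
}

em_univariate <- function(x, par, tol, max_iter, var_floor) {
  n <- length(x)
  w1 <- par$w1; mu1 <- par$mu1; mu2 <- par$mu2; s1 <- par$s1; s2 <- par$s2
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    l1 <- log(w1) + stats::dnorm(x, mu1, s1, log = TRUE)
    l2 <- log(1 - w1) + stats::dnorm(x, mu2, s2, log = TRUE)
    lmax <- pmax(l1, l2)
    lse <- lmax + log(exp(l1 - lmax) + exp(l2 - lmax))
    ll <- sum(lse)
    trace <- c(trace, ll)
    g1 <- exp(l1 - lse)
    n1 <- sum(g1)
    w1 <- n1 / n
    mu1 <- sum(g1 * x) / n1
    mu2 <- sum((1 - g1) * x) / (n - n1)
    s1 <- sqrt(max(sum(g1 * (x - mu1)^2) / n1, var_floor))
    s2 <- sqrt(max(sum((1 - g1) * (x - mu2)^2) / (n - n1), var_floor))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(w1 = w1, w2 = 1 - w1, mu1 = mu1, mu2 = mu2, sigma1 = s1, sigma2 = s2,
       loglik = trace[length(trace)], n_iter = iter, converged = converged,
       loglik_trace = trace)
}

#' Equal-posterior cutoff of a two-component mixture
#'
#' Solves `w1 phi(z; mu1, sigma1) = w2 phi(z; mu2, sigma2)` for the point
#' between the component means where a sample is equally likely to belong to
#' either distribution. With unequal variances this is a quadratic in `z`
#' and the root inside `(mu1, mu2)` is returned; with equal variances the
#' closed form `z = (mu1 + mu2) / 2 + sigma^2 log(w2 / w1) / (mu2 - mu1)`
#' applies.
#'
#' @param model A `gmm_fit` (or anything with `w1`, `w2`, `mu1 < mu2`,
#'   `sigma1`, `sigma2`).
#' @return The cutoff on the scale of the fitted data.
#' @export
equal_posterior_cutoff <- function(model) {
  w1 <- model$w1; w2 <- model$w2
  mu1 <- model$mu1; mu2 <- model$mu2
  s1 <- model$sigma1; s2 <- model$sigma2
  stopifnot(mu1 < mu2)
  K <- log(w1 * s2) - log(w2 * s1)
  a1 <- 1 / (2 * s1^2)
  a2 <- 1 / (2 * s2^2)
  # -a1 (z - mu1)^2 + a2 (z - mu2)^2 + K = 0
  A <- a2 - a1
  B <- 2 * (a1 * mu1 - a2 * mu2)
  C <- a2 * mu2^2 - a1 * mu1^2 + K
  if (abs(A) < 1e-12 * (a1 + a2)) {
    z <- -C / B
    if (z <= mu1 || z >= mu2) stopf("no equal-posterior root in (mu1, mu2): components too overlapped")
    return(z)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) stopf("no equal-posterior root in (mu1, mu2): components too overlapped")
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  inside <- roots > mu1 & roots < mu2
  if (!any(inside)) stopf("no equal-posterior root in (mu1, mu2): components too overlapped")
  roots[inside][1]
}

#' Data-driven biomarker positivity cutoff via Gaussian mixture
#'
#' The full single-cutoff procedure: z-score the log10 biomarker values
#' (using the mean and SD of all values entering the fit), fit a
#' two-component mixture with [fit_two_component_gmm()], and place the
#' cutoff at the equal-posterior point. The standardization pair is stored
#' so the cutoff is expressible on the z, log10, and linear NPQ scales.
#'
#' @param x_log10 Numeric vector of log10 NPQ biomarker values.
#' @param ... Passed to [fit_two_component_gmm()].
#' @return A list of class `mixture_cutoff_model`: the `gmm_fit` fields plus
#'   `z_cutoff`, `cutoff_log10`, `cutoff_linear`, and
#'   `standardization = c(mean, sd)`.
#' @examples
#' x <- c(rnorm(500, 3.45, 0.12), rnorm(460, 3.85, 0.18))
#' mod <- gmm_cutoff(x)
#' c(mod$z_cutoff, mod$cutoff_log10, mod$cutoff_linear)
#' @export
gmm_cutoff <- function(x_log10, ...) {
  x <- x_log10[is.finite(x_log10)]
  ctr <- mean(x)
  scl <- stats::sd(x)
  if (!is.finite(scl) || scl == 0) stopf("biomarker values have zero variance")
  z <- (x - ctr) / scl
  fit <- fit_two_component_gmm(z, ...)
  out <- unclass(fit)
  zc <- tryCatch(equal_posterior_cutoff(fit), error = function(e) NA_real_)
  out$fallback_midpoint <- FALSE
  if (is.na(zc)) {
    # components so overlapped that one dominates everywhere between the
    # means (effectively unimodal data): fall back to the mean midpoint and
    # mark the cutoff low-confidence
    zc <- (fit$mu1 + fit$mu2) / 2
    out$fallback_midpoint <- TRUE
    out$low_confidence <- TRUE
  }
  out$z_cutoff <- zc
  out$cutoff_log10 <- ctr + scl * zc
  out$cutoff_linear <- 10^out$cutoff_log10
  out$standardization <- c(mean = ctr, sd = scl)
  class(out) <- c("mixture_cutoff_model", "gmm_fit")
  out
}

#' @export
print.mixture_cutoff_model <- function(x, ...) {
  cat(sprintf("two-component mixture cutoff: z = %.4f (log10 NPQ %.4f, linear %.2f)\n",
              x$z_cutoff, x$cutoff_log10, x$cutoff_linear))
  cat(sprintf("  components: w = (%.3f, %.3f), mu = (%.3f, %.3f), sigma = (%.3f, %.3f)%s\n",
              x$w1, x$w2, x$mu1, x$mu2, x$sigma1, x$sigma2,
              if (isTRUE(x$low_confidence)) "  [low confidence: overlapping modes]" else ""))
  invisible(x)
}

#' Single cutoff by the Youden index
#'
#' Scans the sorted unique scores as candidate thresholds (classifying
#' `score >= t` as positive against the binary reference) and returns the
#' threshold maximizing sensitivity + specificity - 1, breaking ties toward
#' the smallest threshold. Empirical, non-interpolated: candidate thresholds
#' are observed scores only.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) reference labels, both classes present.
#' @return A list: `threshold`, `youden_j`, `sensitivity`, `specificity`,
#'   `degenerate` (`TRUE` when only one candidate threshold exists).
#' @export
youden_cutoff <- function(scores, labels) {
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  cand <- sort(unique(scores))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  tp <- vapply(cand, function(t) sum(scores[labels] >= t), numeric(1))
  tn <- vapply(cand, function(t) sum(scores[!labels] < t), numeric(1))
  # the integer-valued objective tp*n0 + tn*n1 orders thresholds exactly
  # (it is J * n0 * n1 up to a constant); ties -> smallest threshold
  crit <- tp * n0 + tn * n1
  best <- which(crit == max(crit))[1]
  list(threshold = cand[best], youden_j = tp[best] / n1 + tn[best] / n0 - 1,
       sensitivity = tp[best] / n1, specificity = tn[best] / n0,
       degenerate = length(cand) == 1)
}

#' Dual cutoffs at 95% sensitivity and 95% specificity
#'
#' Derives a lower cutoff (the largest observed threshold keeping
#' sensitivity at or above `target_sens` when `score >= t` is called
#' positive) and an upper cutoff (the smallest observed threshold with
#' specificity at or above `target_spec`), then trichotomizes: scores below
#' the lower cutoff are `low`, above the upper cutoff `high`, and the closed
#' interval between them `intermediate`. Concordance against a reference is
#' typically evaluated on the low/high classes only.
#'
#' @param scores Numeric scores (e.g. log10 biomarker values).
#' @param labels Logical reference status (e.g. amyloid-PET positivity).
#' @param target_sens,target_spec Targets, default 0.95 each.
#' @return A list of class `dual_cutoff`: `lower`, `upper`, the targets, the
#'   achieved sensitivity/specificity at the cutoffs, per-class `counts`
#'   (low/intermediate/high), `class` (factor aligned with `scores`, `NA`
#'   where the score is missing), and `flag` (`"ok"`,
#'   `"empty_intermediate"` when the cutoffs cross and the lower is set to
#'   the upper, or `"target_not_reached"`).
#' @export
dual_cutoffs <- function(scores, labels, target_sens = 0.95,
                         target_spec = 0.95) {
  keep <- is.finite(scores) & !is.na(labels)
  s <- scores[keep]
  l <- as.logical(labels[keep])
  if (length(unique(l)) < 2) stopf("both classes must be present")
  if (sum(l) < 20 || sum(!l) < 20) {
    message(sprintf("dual_cutoffs: only %d positives / %d negatives; cutoffs may be unstable",
                    sum(l), sum(!l)))
  }
  cand <- sort(unique(s))
  sens <- vapply(cand, function(t) mean(s[l] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(s[!l] < t), numeric(1))
  flag <- "ok"
  ok_sens <- sens >= target_sens
  lower <- if (any(ok_sens)) max(cand[ok_sens]) else { flag <- "target_not_reached"; min(cand) }
  ok_spec <- spec >= target_spec
  upper <- if (any(ok_spec)) min(cand[ok_spec]) else { flag <- "target_not_reached"; max(cand) }
  if (lower > upper) {
    flag <- "empty_intermediate"
    lower <- upper
  }
  cls <- classify_dual(scores, lower, upper)
  counts <- table(factor(cls, levels = c("low", "intermediate", "high")))
  structure(list(lower = lower, upper = upper,
                 target_sensitivity = target_sens,
                 target_specificity = target_spec,
                 sensitivity_at_lower = mean(s[l] >= lower),
                 specificity_at_upper = mean(s[!l] < upper),
                 counts = c(low = unname(counts["low"]),
                            intermediate = unname(counts["intermediate"]),
                            high = unname(counts["high"])),
                 class = cls, flag = flag),
            class = "dual_cutoff")
}

#' @rdname dual_cutoffs
#' @param lower,upper Cutoffs on the score scale.
#' @return `classify_dual()`: factor with levels low/intermediate/high.
#' @export
classify_dual <- function(scores, lower, upper) {
  cls <- ifelse(scores < lower, "low",
                ifelse(scores > upper, "high", "intermediate"))
  factor(cls, levels = c("low", "intermediate", "high"))
}

#' @export
print.dual_cutoff <- function(x, ...) {
  n <- sum(x$counts)
  cat(sprintf("dual cutoffs: lower %.4f (sens %.3f), upper %.4f (spec %.3f)%s\n",
              x$lower, x$sensitivity_at_lower, x$upper,
              x$specificity_at_upper,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  cat(sprintf("  classes: low %d (%.2f%%), intermediate %d (%.2f%%), high %d (%.2f%%)\n",
              x$counts["low"], 100 * x$counts["low"] / n,
              x$counts["intermediate"], 100 * x$counts["intermediate"] / n,
              x$counts["high"], 100 * x$counts["high"] / n))
  invisible(x)
}

#' Reference biomarker status from imaging or CSF
#'
#' Binary positivity labels from the standard cutpoints: amyloid-PET above
#' 20 Centiloids, tau-PET above 1.5 SUVR (tau signature region), or a CSF
#' Abeta42/Abeta40 ratio below 0.0673. Values exactly at an imaging
#' cutpoint are negative (the rule is strict `>`); a CSF ratio exactly at
#' the cutpoint is negative (strict `<`). Missing measurements give `NA`.
#'
#' @param meta Sample metadata with `amyloid_pet`, `tau_pet`,
#'   `csf_ab_ratio` columns as applicable.
#' @param modality `"amyloid"`, `"tau"`, or `"csf"`.
#' @param cfg A [run_config()] supplying the cutpoints.
#' @return Logical vector aligned with `meta` rows, named by `sample_id`.
#' @export
pet_reference <- function(meta, modality = c("amyloid", "tau", "csf"),
                          cfg = run_config()) {
  modality <- match.arg(modality)
  out <- switch(modality,
    amyloid = meta$amyloid_pet > cfg$amyloid_cutpoint,
    tau = meta$tau_pet > cfg$tau_cutpoint,
    csf = meta$csf_ab_ratio < cfg$csf_cutpoint
  )
  names(out) <- meta$sample_id
  out
}
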