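#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic of the
#' scores (midranks for ties): the probability that a random case scores
#' higher than a random control, with ties counting one half.
#'
#' @param score Numeric scores.
#' @param label Logical (or 0/1) outcome, both classes present.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Covariate-adjusted logistic classification with ROC/AUC
#'
#' Maximum-likelihood logistic regression of a binary outcome on one or
#' more protein features plus adjustment covariates (age at draw and sex by
#' default). The classification score is the fitted linear predictor of the
#' full model; AUC is its rank statistic ([rank_auc()]), with a 95%
#' confidence interval from a stratified nonparametric bootstrap of the
#' scores (cases and controls resampled separately; the model is not
#' refit per replicate).
#'
#' @param data Data.frame holding the outcome, features and covariates.
#' @param outcome Name of a logical/binary column.
#' @param features Character vector of feature column names.
#' @param adjust Covariate column names (default `age_at_draw`, `sex`);
#'   use `character(0)` for an unadjusted model.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return A list of class `prediction_record`: `label`, `predictors`,
#'   `auc`, `ci_lower`, `ci_upper`, `n_cases`, `n_controls`, `separation`
#'   flag, and the fitted `model`.
#' @export
fit_logistic_auc <- function(data, outcome, features,
                             adjust = c("age_at_draw", "sex"),
                             n_boot = 2000, conf = 0.95, seed = 1) {
  cols <- c(outcome, features, adjust)
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  df <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  y <- as.logical(df[[outcome]])
  if (sum(y) < 5 || sum(!y) < 5) {
    stopf("need at least 5 samples in each class (got %d cases, %d controls)",
          sum(y), sum(!y))
  }
  rhs <- paste(c(features, adjust), collapse = " + ")
  df$.outcome <- y
  fml <- stats::as.formula(paste(".outcome ~", rhs))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  score <- as.numeric(stats::predict(fit, type = "link"))
  auc <- rank_auc(score, y)
  # perfect separation of the scores: report AUC 1 but flag it
  if (min(score[y]) > max(score[!y])) separation <- TRUE
  ci <- with_seed(seed, {
    idx1 <- which(y)
    idx0 <- which(!y)
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- c(sample(idx1, length(idx1), replace = TRUE),
             sample(idx0, length(idx0), replace = TRUE))
      rank_auc(score[i], y[i])
    }, numeric(1))
    stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE, type = 7)
  })
  structure(list(label = outcome, predictors = c(features, adjust),
                 auc = auc, ci_lower = ci[1], ci_upper = ci[2],
                 n_cases = sum(y), n_controls = sum(!y),
                 separation = separation, model = fit),
            class = "prediction_record")
}

#' @export
print.prediction_record <- function(x, ...) {
  cat(sprintf("%s ~ %s: AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls%s\n",
              x$label, paste(x$predictors, collapse = " + "), x$auc,
              x$ci_lower, x$ci_upper, x$n_cases, x$n_controls,
              if (x$separation) " [perfect separation]" else ""))
  invisible(x)
}

#' Protein ratio feature
#'
#' Ratio of two analytes computed on the log10 scale as
#' `log10(numerator) - log10(denominator)`, i.e. the log of the linear NPQ
#' ratio. Missing wherever either analyte is missing.
#'
#' @param m An [npq_matrix()] on the log10 scale.
#' @param numerator,denominator Distinct analyte IDs.
#' @return Named numeric vector (one value per sample).
#' @export
ratio_feature <- function(m, numerator, denominator) {
  stopifnot(inherits(m, "npq_matrix"))
  if (npq_scale(m) != "log10") {
    stopf("ratio_feature expects a log10-scale matrix; use transform_scale()")
  }
  if (identical(numerator, denominator)) {
    stopf("numerator and denominator must differ")
  }
  for (a in c(numerator, denominator)) {
    if (!a %in% colnames(m)) stopf("analyte %s not in matrix", a)
  }
  out <- m[, numerator] - m[, denominator]
  names(out) <- rownames(m)
  out
}

#' Time-horizon progression prediction
#'
#' AUC of a baseline feature for predicting conversion to symptomatic AD
#' within a time horizon. The outcome is 1 for participants converting
#' within `horizon_years` of draw and 0 for participants followed (without
#' conversion) at least to the horizon; participants censored before the
#' horizon without converting are excluded, and conversions after the
#' horizon count as non-converters (they were unimpaired at the horizon).
#'
#' @param meta Sample metadata (baseline-unimpaired participants with
#'   follow-up; see [build_time_to_event()]).
#' @param feature Named numeric vector of baseline feature values (names =
#'   sample IDs), e.g. a biomarker column of the NPQ matrix.
#' @param horizon_years Horizon in years (e.g. 5, 10, 15). A horizon beyond
#'   the longest follow-up reduces to the any-time conversion outcome.
#' @param ... Passed to [fit_logistic_auc()].
#' @return A `prediction_record`.
#' @export
horizon_auc <- function(meta, feature, horizon_years, ...) {
  tte <- build_time_to_event(meta)
  idx <- match(tte$sample_id, meta$sample_id)
  df <- data.frame(
    feature = as.numeric(feature[tte$sample_id]),
    age_at_draw = meta$age_at_draw[idx],
    sex = meta$sex[idx],
    time = tte$time, event = tte$event
  )
  if (horizon_years >= max(df$time)) {
    # horizon beyond the longest follow-up: any-time conversion outcome
    df$outcome <- df$event
  } else {
    converted <- df$event & df$time <= horizon_years
    at_risk_to_horizon <- df$time >= horizon_years | df$event
    df <- df[converted | at_risk_to_horizon, , drop = FALSE]
    df$outcome <- df$event & df$time <= horizon_years
  }
  if (sum(df$outcome) < 5) {
    stopf("fewer than 5 converters within %g years", horizon_years)
  }
  fit_logistic_auc(df, outcome = "outcome", features = "feature", ...)
}
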