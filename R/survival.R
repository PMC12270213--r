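#' Build time-to-event records for progression to symptomatic AD
#'
#' For baseline cognitively-unimpaired participants (diagnosis `CO` at
#' draw) with follow-up data: converters get
#' `time = age_at_onset - age_at_draw` with `event = TRUE`; non-converters
#' get `time = age_at_last_followup - age_at_draw` with `event = FALSE`.
#' Rows with nonpositive or missing times (e.g. onset recorded before the
#' draw) are dropped and counted in `attr(, "n_dropped")`. When the same
#' participant has several samples, the earliest draw is used.
#'
#' A participant counts as a converter when `converted_to_ad` is `TRUE`
#' (if that column exists) or, otherwise, when `age_at_onset` is present.
#'
#' @param meta Sample metadata.
#' @return Data.frame with `participant_id`, `sample_id`, `time` (years),
#'   `event` (logical), plus attribute `n_dropped`.
#' @export
build_time_to_event <- function(meta) {
  co <- meta[meta$diagnosis == "CO", , drop = FALSE]
  if (nrow(co) == 0) stopf("no baseline-unimpaired (CO) participants")
  if (anyDuplicated(co$participant_id)) {
    ord <- order(co$participant_id, co$age_at_draw)
    co <- co[ord, ][!duplicated(co$participant_id[ord]), , drop = FALSE]
  }
  converter <- if ("converted_to_ad" %in% names(co)) {
    flag <- as.logical(co$converted_to_ad)
    !is.na(flag) & flag
  } else {
    !is.na(co$age_at_onset)
  }
  time <- ifelse(converter, co$age_at_onset - co$age_at_draw,
                 co$age_at_last_followup - co$age_at_draw)
  ok <- !is.na(time) & time > 0
  out <- data.frame(participant_id = co$participant_id[ok],
                    sample_id = co$sample_id[ok],
                    time = time[ok], event = converter[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Per-protein proportional-hazards fits
#'
#' One Cox model per analyte for progression to symptomatic AD: the analyte
#' (standardized to SD 1 on its observed values) plus age at draw and sex,
#' Efron tie handling by default. Hazard ratios are per SD of log10 NPQ.
#' Wald p-values are BH-adjusted across analytes. Analytes whose fit does
#' not converge are flagged, not dropped.
#'
#' @param tte Output of [build_time_to_event()].
#' @param m An [npq_matrix()] (log10 scale) containing the `tte` samples.
#' @param meta Sample metadata (for age and sex).
#' @param ties Tie method passed to [survival::coxph()] (`"efron"` default,
#'   `"breslow"` available).
#' @param min_events Minimum number of events required (default 10).
#' @return Data.frame: `analyte_id`, `hr`, `ci_lower`, `ci_upper`, `p_raw`,
#'   `p_fdr`, `n_events`, `n_at_risk`, `flag`.
#' @export
fit_cox_per_protein <- function(tte, m, meta, ties = c("efron", "breslow"),
                                min_events = 10) {
  ties <- match.arg(ties)
  stopifnot(inherits(m, "npq_matrix"))
  tte <- tte[tte$sample_id %in% rownames(m), , drop = FALSE]
  if (sum(tte$event) < min_events) {
    stopf("only %d events (need >= %d)", sum(tte$event), min_events)
  }
  idx <- match(tte$sample_id, meta$sample_id)
  base <- data.frame(time = tte$time, event = tte$event,
                     age_at_draw = meta$age_at_draw[idx],
                     male = male_indicator(meta$sex[idx]))
  v <- unclass(m)[tte$sample_id, , drop = FALSE]
  res <- lapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    obs <- !is.na(x) & stats::complete.cases(base)
    rec <- data.frame(analyte_id = colnames(v)[j], hr = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      p_raw = NA_real_, n_events = sum(base$event[obs]),
                      n_at_risk = sum(obs), flag = "ok",
                      stringsAsFactors = FALSE)
    sdx <- stats::sd(x[obs])
    if (!is.finite(sdx) || sdx == 0) {
      rec$flag <- "degenerate"
      return(rec)
    }
    d <- base[obs, , drop = FALSE]
    d$z <- (x[obs] - mean(x[obs])) / sdx
    fit <- tryCatch(
      survival::coxph(survival::Surv(time, event) ~ z + age_at_draw + male,
                      data = d, ties = ties),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) {
      # refit without suppressing warnings to keep the estimate but flag it
      fit2 <- tryCatch(suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ z + age_at_draw + male,
                        data = d, ties = ties)), error = function(e) NULL)
      if (is.null(fit2)) {
        rec$flag <- "no_fit"
        return(rec)
      }
      rec$flag <- "not_converged"
      fit <- fit2
    }
    sm <- summary(fit)
    rec$hr <- unname(sm$conf.int["z", "exp(coef)"])
    rec$ci_lower <- unname(sm$conf.int["z", "lower .95"])
    rec$ci_upper <- unname(sm$conf.int["z", "upper .95"])
    rec$p_raw <- unname(sm$coefficients["z", "Pr(>|z|)"])
    rec
  })
  out <- do.call(rbind, res)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_fdr[ok] <- adjust_fdr(out$p_raw[ok])
  out[, c("analyte_id", "hr", "ci_lower", "ci_upper", "p_raw", "p_fdr",
          "n_events", "n_at_risk", "flag")]
}

#' Kaplan-Meier comparison of cutoff-defined biomarker groups
#'
#' Product-limit survival curves for biomarker-high vs biomarker-low groups
#' (e.g. from the mixture cutoff) with a two-sided log-rank test.
#' Optionally also returns covariate-adjusted curves by direct
#' standardization: a Cox model on group plus covariates is fit, and each
#' group's curve is the average of the model's predicted survival over the
#' pooled covariate distribution (g-formula averaging). The unadjusted
#' Kaplan-Meier curves are the primary output.
#'
#' @param tte Output of [build_time_to_event()].
#' @param group Factor/character vector aligned with `tte` rows (two
#'   levels), e.g. `"high"`/`"low"`.
#' @param covariates Optional data.frame (aligned with `tte` rows) of
#'   adjustment covariates for the adjusted curves.
#' @param min_events Minimum total events (default 5).
#' @return A list of class `km_comparison`: `fit` (a
#'   [survival::survfit()] object), `logrank_chisq`, `logrank_p`,
#'   `n_events`, `groups`, and `adjusted` (data.frame of standardized
#'   curves, or `NULL`).
#' @export
km_by_cutoff <- function(tte, group, covariates = NULL, min_events = 5) {
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(droplevels(group)) < 2) {
    stopf("each group must be non-empty")
  }
  group <- droplevels(group)
  if (sum(tte$event) < min_events) {
    stopf("only %d events (need >= %d)", sum(tte$event), min_events)
  }
  d <- data.frame(time = tte$time, event = tte$event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- stats::pchisq(lr$chisq, df = length(lr$n) - 1, lower.tail = FALSE)
  adjusted <- NULL
  if (!is.null(covariates)) {
    dc <- cbind(d, covariates)
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ group +",
      paste(names(covariates), collapse = " + ")))
    cox <- survival::coxph(fml, data = dc)
    times <- sort(unique(d$time[d$event]))
    adjusted <- do.call(rbind, lapply(levels(group), function(g) {
      nd <- dc
      nd$group <- factor(g, levels = levels(group))
      sf <- survival::survfit(cox, newdata = nd)
      surv <- summary(sf, times = times, extend = TRUE)$surv
      surv <- matrix(surv, nrow = length(times))
      data.frame(group = g, time = times, surv = rowMeans(surv))
    }))
  }
  structure(list(fit = fit, logrank_chisq = unname(lr$chisq), logrank_p = p,
                 n_events = sum(d$event), groups = levels(group),
                 adjusted = adjusted),
            class = "km_comparison")
}

#' @export
print.km_comparison <- function(x, ...) {
  cat(sprintf("Kaplan-Meier comparison (%s): %d events, log-rank chisq %.2f, p = %.3g\n",
              paste(x$groups, collapse = " vs "), x$n_events,
              x$logrank_chisq, x$logrank_p))
  invisible(x)
}
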