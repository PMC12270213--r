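#' Estimate surrogate variables by residual SVD
#'
#' Captures latent batch/technical structure not explained by the primary
#' design: missing cells are imputed by seeded random draws from the
#' observed values of the same analyte, each analyte is regressed on the
#' primary design (diagnosis/phenotype plus age and sex), the residual
#' matrix is standardized analyte-wise to unit variance, and the top
#' `n_sv` left singular vectors in sample space are returned. This is a
#' deterministic approximation to permutation-based surrogate variable
#' analysis: the number of factors is fixed by the caller rather than
#' estimated.
#'
#' @param m An [npq_matrix()] after QC.
#' @param meta Metadata containing `sample_id` and the design columns.
#' @param design One-sided formula for the primary design, evaluated in
#'   `meta` (default `~ diagnosis + age_at_draw + sex`).
#' @param n_sv Number of surrogate variables (must be < min(dim)).
#' @param seed Seed for the imputation draws.
#' @return Data.frame with `sample_id` and columns `sv1 ... sv<n_sv>`; each
#'   SV has mean zero and the set is mutually orthogonal.
#' @export
estimate_surrogate_variables <- function(m, meta,
                                         design = ~ diagnosis + age_at_draw + sex,
                                         n_sv = 2, seed = 1) {
  stopifnot(inherits(m, "npq_matrix"))
  if (n_sv >= min(dim(m))) {
    stopf("n_sv = %d must be smaller than both matrix dimensions (%d x %d)",
          n_sv, nrow(m), ncol(m))
  }
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id))) stopf("metadata missing some matrix samples")
  X <- stats::model.matrix(design, data = meta)
  if (nrow(X) != nrow(m)) stopf("design has missing covariate values")
  v <- unclass(m)
  with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (any(miss)) {
        obs <- v[!miss, j]
        if (length(obs) == 0) stopf("analyte %s has no observed values",
                                    colnames(v)[j])
        v[miss, j] <- sample(obs, sum(miss), replace = TRUE)
      }
    }
  })
  fit <- stats::lm.fit(X, v)
  R <- as.matrix(fit$residuals)
  sds <- apply(R, 2, stats::sd)
  sds[sds < 1e-12] <- 1
  R <- sweep(R, 2, sds, "/")
  sv <- svd(R, nu = n_sv, nv = 0)$u
  colnames(sv) <- paste0("sv", seq_len(n_sv))
  data.frame(sample_id = rownames(m), sv, stringsAsFactors = FALSE,
             row.names = NULL)
}

contrast_kinds <- function() {
  list(disease = c("AD_vs_CO", "DLB_vs_CO", "FTD_vs_CO", "PD_vs_CO"),
       phenotype = c("amyloid_pet", "tau_pet", "csf_ab_ratio", "cdr"))
}

#' Per-analyte differential abundance
#'
#' Ordinary least squares of log10 NPQ on a predictor plus age at draw, sex,
#' and (optionally) surrogate variables, one model per analyte on that
#' analyte's complete cases. For disease contrasts (`"AD_vs_CO"`, ...) the
#' predictor is a case indicator with controls as reference and only the two
#' groups' samples enter; for endophenotypes (`"amyloid_pet"`, `"tau_pet"`,
#' `"csf_ab_ratio"`, `"cdr"`) the phenotype is the continuous predictor on
#' all samples where it is observed. P-values are two-sided t-tests on the
#' predictor coefficient; Benjamini-Hochberg adjustment is applied across
#' analytes within the contrast.
#'
#' @param m An [npq_matrix()] on the log10 scale.
#' @param meta Sample metadata.
#' @param contrast One of the disease or phenotype contrast labels above.
#' @param svs Optional surrogate-variable data.frame from
#'   [estimate_surrogate_variables()]; `NULL` fits without SVs.
#' @param one_per_participant Keep only the latest draw per participant
#'   (default `TRUE`, matching a unique-participant analysis).
#' @param min_cases Below this case count a warning is logged (the model is
#'   still fit).
#' @return Data.frame with one row per analyte: `analyte_id`, `contrast`,
#'   `beta`, `se`, `p_raw`, `p_fdr`, `n_used`, `flag` (`"ok"`, or
#'   `"degenerate"` for analytes with no residual variance, which report
#'   `beta = 0` and missing p).
#' @export
fit_associations <- function(m, meta, contrast, svs = NULL,
                             one_per_participant = TRUE, min_cases = 10) {
  stopifnot(inherits(m, "npq_matrix"))
  kinds <- contrast_kinds()
  if (!contrast %in% unlist(kinds)) {
    stopf("unknown contrast '%s' (expected one of %s)", contrast,
          paste(unlist(kinds), collapse = ", "))
  }
  meta <- meta[meta$sample_id %in% rownames(m), , drop = FALSE]
  if (one_per_participant && anyDuplicated(meta$participant_id)) {
    ord <- order(meta$participant_id, -meta$age_at_draw)
    meta <- meta[ord, ][!duplicated(meta$participant_id[ord]), , drop = FALSE]
  }

  if (contrast %in% kinds$disease) {
    case <- sub("_vs_CO", "", contrast)
    meta <- meta[meta$diagnosis %in% c(case, "CO"), , drop = FALSE]
    predictor <- as.integer(meta$diagnosis == case)
    if (sum(predictor) < min_cases) {
      warnf("contrast %s has only %d cases", contrast, sum(predictor))
    }
  } else {
    predictor <- meta[[contrast]]
    keep <- !is.na(predictor)
    meta <- meta[keep, , drop = FALSE]
    predictor <- predictor[keep]
  }

  df <- data.frame(predictor = predictor,
                   age_at_draw = meta$age_at_draw,
                   male = male_indicator(meta$sex))
  if (!is.null(svs)) {
    idx <- match(meta$sample_id, svs$sample_id)
    for (col in setdiff(names(svs), "sample_id")) {
      sv_col <- svs[[col]][idx]
      # constant SVs (e.g. all-zero placeholders) carry no information and
      # would only make the design singular
      if (stats::sd(sv_col, na.rm = TRUE) > 0) df[[col]] <- sv_col
    }
  }
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  meta <- meta[cc, , drop = FALSE]
  X <- as.matrix(cbind(intercept = 1, df))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stopf("rank-deficient design; collinear column(s): %s",
          paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
                collapse = ", "))
  }
  v <- unclass(m)[meta$sample_id, , drop = FALSE]

  res <- lapply(seq_len(ncol(v)), function(j) {
    y <- v[, j]
    obs <- !is.na(y)
    n_used <- sum(obs)
    if (n_used <= ncol(X) || stats::sd(y[obs]) == 0) {
      return(data.frame(analyte_id = colnames(v)[j], contrast = contrast,
                        beta = 0, se = NA_real_, p_raw = NA_real_,
                        n_used = n_used, flag = "degenerate"))
    }
    Xo <- X[obs, , drop = FALSE]
    fit <- stats::lm.fit(Xo, y[obs])
    if (fit$df.residual <= 0) {
      return(data.frame(analyte_id = colnames(v)[j], contrast = contrast,
                        beta = 0, se = NA_real_, p_raw = NA_real_,
                        n_used = n_used, flag = "degenerate"))
    }
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / fit$df.residual
    XtXinv <- tryCatch(chol2inv(chol(crossprod(Xo))), error = function(e) NULL)
    if (is.null(XtXinv)) {
      return(data.frame(analyte_id = colnames(v)[j], contrast = contrast,
                        beta = 0, se = NA_real_, p_raw = NA_real_,
                        n_used = n_used, flag = "degenerate"))
    }
    k <- which(colnames(X) == "predictor")
    beta <- fit$coefficients[k]
    se <- sqrt(sigma2 * XtXinv[k, k])
    tval <- beta / se
    p <- 2 * stats::pt(abs(tval), fit$df.residual, lower.tail = FALSE)
    data.frame(analyte_id = colnames(v)[j], contrast = contrast,
               beta = unname(beta), se = unname(se), p_raw = unname(p),
               n_used = n_used, flag = "ok")
  })
  out <- do.call(rbind, res)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p_raw)
  out$p_fdr[ok] <- adjust_fdr(out$p_raw[ok])
  out[, c("analyte_id", "contrast", "beta", "se", "p_raw", "p_fdr",
          "n_used", "flag")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment for one contrast's p-values:
#' `p_fdr(i) = min over j >= i of m * p(j) / j`, capped at 1. The output is
#' invariant under permutation of the input order and never smaller than the
#' raw p-value.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
adjust_fdr <- function(p) {
  if (is.data.frame(p)) p <- p$p_raw
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Compare effect sizes between two contrasts
#'
#' On the analytes significant in at least one of two association tables
#' (BH-adjusted p below `level`, or raw p under the relaxed `"nominal"`
#' rule used when one contrast is underpowered), computes the Pearson
#' correlation of effect sizes, regresses the second contrast's betas on the
#' first's, and flags analytes falling outside the 95% per-point prediction
#' band or showing discordant effect signs.
#'
#' @param table_a,table_b Association tables from [fit_associations()].
#' @param selection `"fdr"` (default) or `"nominal"`.
#' @param level Selection significance level (default 0.05).
#' @param band_level Prediction-band coverage (default 0.95).
#' @return A list of class `effect_comparison`: `contrast_pair`, `r`, `p_r`,
#'   `n_shared`, `n_selected`, `band_outliers` (data.frame with
#'   `analyte_id`, `side`, betas), `discordant_sign` (analyte IDs), and the
#'   merged `data` with band bounds.
#' @export
compare_effect_sizes <- function(table_a, table_b,
                                 selection = c("fdr", "nominal"),
                                 level = 0.05, band_level = 0.95) {
  selection <- match.arg(selection)
  mg <- merge(table_a, table_b, by = "analyte_id", suffixes = c("_a", "_b"))
  if (nrow(mg) < 3) stopf("fewer than 3 shared analytes")
  pa <- if (selection == "fdr") mg$p_fdr_a else mg$p_raw_a
  pb <- if (selection == "fdr") mg$p_fdr_b else mg$p_raw_b
  sel <- (!is.na(pa) & pa < level) | (!is.na(pb) & pb < level)
  dat <- mg[sel, , drop = FALSE]
  if (nrow(dat) < 3) stopf("fewer than 3 selected analytes")

  ct <- stats::cor.test(dat$beta_a, dat$beta_b)
  fit <- stats::lm(beta_b ~ beta_a, data = dat)
  band <- stats::predict(fit, newdata = dat, interval = "prediction",
                         level = band_level)
  outside <- dat$beta_b < band[, "lwr"] | dat$beta_b > band[, "upr"]
  side <- ifelse(dat$beta_b > band[, "upr"], "above", "below")
  discordant <- sign(dat$beta_a) * sign(dat$beta_b) < 0
  dat$band_lower <- band[, "lwr"]
  dat$band_upper <- band[, "upr"]
  dat$band_outlier <- outside
  dat$discordant_sign <- discordant
  structure(list(
    contrast_pair = c(table_a$contrast[1], table_b$contrast[1]),
    r = unname(ct$estimate), p_r = ct$p.value,
    n_shared = nrow(mg), n_selected = nrow(dat),
    band_outliers = data.frame(analyte_id = dat$analyte_id[outside],
                               side = side[outside],
                               beta_a = dat$beta_a[outside],
                               beta_b = dat$beta_b[outside],
                               stringsAsFactors = FALSE),
    discordant_sign = dat$analyte_id[discordant],
    fit = fit, data = dat
  ), class = "effect_comparison")
}

#' @export
print.effect_comparison <- function(x, ...) {
  cat(sprintf("effect-size comparison %s vs %s: r = %.3f (p = %.3g), %d selected of %d shared\n",
              x$contrast_pair[1], x$contrast_pair[2], x$r, x$p_r,
              x$n_selected, x$n_shared))
  cat(sprintf("  band outliers: %d; discordant signs: %d\n",
              nrow(x$band_outliers), length(x$discordant_sign)))
  invisible(x)
}
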