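#' Mask IQR outliers per analyte
#'
#' Flags, per analyte, values falling outside `k` times the interquartile
#' range below the first or above the third quartile and replaces them with
#' missing values. Quantiles use linear interpolation on the non-missing
#' values (type 7, `h = (n - 1) p + 1`). The pass is single-shot: fences are
#' computed once and not re-derived after masking. Analytes with fewer than
#' four non-missing values have no defined fences and pass through unmasked
#' with a flag.
#'
#' @param m An [npq_matrix()].
#' @param k Positive fence multiplier (default 1.5).
#' @return A list with `matrix` (masked copy of `m`) and `analytes`, a
#'   per-analyte data.frame with the fences, IQR, number of masked cells and
#'   a `fences_defined` flag.
#' @export
mask_iqr_outliers <- function(m, k = 1.5) {
  stopifnot(inherits(m, "npq_matrix"))
  if (k <= 0) stopf("IQR multiplier k must be positive")
  out <- m
  rec <- data.frame(analyte_id = colnames(m), q1 = NA_real_, q3 = NA_real_,
                    iqr = NA_real_, lower_fence = NA_real_,
                    upper_fence = NA_real_, n_outliers_masked = 0L,
                    fences_defined = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    obs <- !is.na(x)
    if (sum(obs) < 4) next
    q <- stats::quantile(x[obs], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - k * iqr
    hi <- q[2] + k * iqr
    flag <- obs & (x < lo | x > hi)
    out[flag, j] <- NA_real_
    rec[j, c("q1", "q3", "iqr", "lower_fence", "upper_fence")] <-
      c(q, iqr, lo, hi)
    rec$n_outliers_masked[j] <- sum(flag)
    rec$fences_defined[j] <- TRUE
  }
  list(matrix = out, analytes = rec)
}

call_rates <- function(m) {
  list(analyte = colMeans(!is.na(m)), sample = rowMeans(!is.na(m)))
}

#' Two-step call-rate filter
#'
#' Removes low-quality analytes and samples by call rate (the proportion of
#' non-missing measurements) in two passes: first at `step1` (default 65%),
#' then, after recomputing call rates on the surviving submatrix, at `step2`
#' (default 85%). Within each pass analytes are filtered before samples, and
#' sample call rates are computed on the already-reduced analyte set. The
#' staged recomputation retains borderline analytes and samples that a
#' single 85% pass would discard.
#'
#' @param m An [npq_matrix()] (typically after [mask_iqr_outliers()]).
#' @param step1,step2 Call-rate thresholds in (0, 1], `step1 <= step2`.
#' @return A list with `matrix` (the retained submatrix, values untouched),
#'   `analytes` and `samples`: data.frames with initial call rate, call rate
#'   entering step 2 (`NA` if removed at step 1), and a `kept` flag.
#' @export
call_rate_filter <- function(m, step1 = 0.65, step2 = 0.85) {
  stopifnot(inherits(m, "npq_matrix"))
  if (!(step1 > 0 && step1 <= 1 && step2 > 0 && step2 <= 1)) {
    stopf("call-rate thresholds must lie in (0, 1]")
  }
  if (step1 > step2) stopf("step1 must not exceed step2")
  if (nrow(m) == 0 || ncol(m) == 0) stopf("empty matrix")
  scl <- npq_scale(m)
  m <- unclass(m)

  arec <- data.frame(analyte_id = colnames(m),
                     call_rate_initial = colMeans(!is.na(m)),
                     call_rate_after_step1 = NA_real_, kept = FALSE,
                     stringsAsFactors = FALSE, row.names = NULL)
  srec <- data.frame(sample_id = rownames(m),
                     call_rate_initial = rowMeans(!is.na(m)),
                     call_rate_after_step1 = NA_real_, kept = FALSE,
                     stringsAsFactors = FALSE, row.names = NULL)

  # Step 1 at `step1`: analytes, then samples on the reduced analyte set.
  keep_a <- arec$call_rate_initial >= step1
  sub <- m[, keep_a, drop = FALSE]
  sr1 <- rowMeans(!is.na(sub))
  keep_s <- sr1 >= step1
  sub <- sub[keep_s, , drop = FALSE]

  # Step 2 at `step2` on recomputed call rates.
  ar2 <- colMeans(!is.na(sub))
  keep_a2 <- ar2 >= step2
  sub <- sub[, keep_a2, drop = FALSE]
  sr2 <- rowMeans(!is.na(sub))
  keep_s2 <- sr2 >= step2
  sub <- sub[keep_s2, , drop = FALSE]

  if (ncol(sub) == 0) {
    stopf("all analytes removed (step 1: %d of %d, step 2: %d of %d)",
          sum(!keep_a), ncol(m), sum(!keep_a2), length(keep_a2))
  }
  arec$call_rate_after_step1[match(names(ar2), arec$analyte_id)] <- ar2
  srec$call_rate_after_step1[match(names(sr2), srec$sample_id)] <- sr2
  arec$kept <- arec$analyte_id %in% colnames(sub)
  srec$kept <- srec$sample_id %in% rownames(sub)
  attr(sub, "scale") <- NULL
  list(matrix = npq_matrix(sub, scale = scl),
       analytes = arec, samples = srec)
}

#' Per-analyte and per-sample QC report
#'
#' Combines the outlier-masking and call-rate records with descriptive
#' quality metrics: the coefficient of variation (sample SD over mean,
#' computed on the linear NPQ scale) and, when supplied, a per-analyte
#' limit-of-detection flag rate. CV and LOD are reported only - they never
#' influence which analytes or samples are kept.
#'
#' @param masked Result of [mask_iqr_outliers()].
#' @param filtered Result of [call_rate_filter()].
#' @param lod Optional named per-analyte vector (e.g. fraction of
#'   measurements below the limit of detection) passed through as
#'   `lod_flag_rate`.
#' @return A list with data.frames `analytes` (call rates, outliers masked,
#'   IQR, CV, LOD, kept flag) and `samples` (call rates, kept flag).
#' @export
qc_report <- function(masked, filtered, lod = NULL) {
  arec <- merge(filtered$analytes,
                masked$analytes[, c("analyte_id", "iqr", "n_outliers_masked",
                                    "fences_defined")],
                by = "analyte_id", sort = FALSE)
  lin <- transform_scale(filtered$matrix, "linear")
  cv <- rep(NA_real_, nrow(arec))
  idx <- match(colnames(lin), arec$analyte_id)
  cv[idx] <- apply(lin, 2, function(x) {
    mu <- mean(x, na.rm = TRUE)
    if (!is.finite(mu) || mu == 0) NA_real_ else stats::sd(x, na.rm = TRUE) / mu
  })
  arec$cv <- cv
  arec$lod_flag_rate <- if (is.null(lod)) NA_real_ else
    as.numeric(lod[arec$analyte_id])
  arec <- arec[, c("analyte_id", "call_rate_initial", "call_rate_after_step1",
                   "n_outliers_masked", "iqr", "cv", "lod_flag_rate",
                   "fences_defined", "kept")]
  list(analytes = arec, samples = filtered$samples)
}

#' Run the full QC stage
#'
#' Convenience wrapper: IQR outlier masking, two-step call-rate filtering,
#' and the QC report in one call.
#'
#' @param m An [npq_matrix()].
#' @param cfg A [run_config()] supplying `iqr_k`, `call_rate_step1`,
#'   `call_rate_step2`.
#' @param lod Optional per-analyte LOD vector for [qc_report()].
#' @return A list with `matrix` (QC'd submatrix), `analytes`, `samples`.
#' @export
run_qc <- function(m, cfg = run_config(), lod = NULL) {
  masked <- mask_iqr_outliers(m, k = cfg$iqr_k)
  filtered <- call_rate_filter(masked$matrix, step1 = cfg$call_rate_step1,
                               step2 = cfg$call_rate_step2)
  rep <- qc_report(masked, filtered, lod = lod)
  list(matrix = filtered$matrix, analytes = rep$analytes,
       samples = rep$samples)
}
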