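#' Per-analyte cross-run / cross-platform correlations
#'
#' Pearson correlation of paired measurements for every shared analyte,
#' computed on pairwise-complete samples. Samples are paired by shared
#' sample IDs, or by an explicit two-column pairing table (IDs in run A,
#' IDs in run B) for cross-platform comparisons where IDs differ; analytes
#' can similarly be matched by an `analyte_map` when the platforms name
#' proteins differently. Analytes with fewer than three complete pairs get
#' a missing correlation and a flag.
#'
#' @param m_a,m_b Two [npq_matrix()] objects on the same scale.
#' @param pairing Optional data.frame with columns `sample_a`, `sample_b`;
#'   default pairs identical sample IDs.
#' @param analyte_map Optional data.frame with columns `analyte_a`,
#'   `analyte_b`; default matches identical analyte IDs.
#' @return Data.frame (`analyte_id`, `analyte_id_b`, `r`, `p_r`, `n_pairs`,
#'   `iqr_run1`, `flag`) with attributes `mean_r` (mean correlation across
#'   analytes) and `frac_above_0.7`.
#' @export
paired_correlations <- function(m_a, m_b, pairing = NULL, analyte_map = NULL) {
  stopifnot(inherits(m_a, "npq_matrix"), inherits(m_b, "npq_matrix"))
  if (npq_scale(m_a) != npq_scale(m_b)) {
    stopf("matrices are on different scales (%s vs %s)",
          npq_scale(m_a), npq_scale(m_b))
  }
  if (is.null(pairing)) {
    shared <- intersect(rownames(m_a), rownames(m_b))
    pairing <- data.frame(sample_a = shared, sample_b = shared)
  }
  if (nrow(pairing) < 3) stopf("fewer than 3 paired samples")
  if (is.null(analyte_map)) {
    shared_a <- intersect(colnames(m_a), colnames(m_b))
    analyte_map <- data.frame(analyte_a = shared_a, analyte_b = shared_a)
  }
  if (nrow(analyte_map) == 0) stopf("no shared analytes")
  va <- unclass(m_a)[pairing$sample_a, , drop = FALSE]
  vb <- unclass(m_b)[pairing$sample_b, , drop = FALSE]
  res <- lapply(seq_len(nrow(analyte_map)), function(k) {
    x <- va[, analyte_map$analyte_a[k]]
    y <- vb[, analyte_map$analyte_b[k]]
    ok <- !is.na(x) & !is.na(y)
    rec <- data.frame(analyte_id = analyte_map$analyte_a[k],
                      analyte_id_b = analyte_map$analyte_b[k],
                      r = NA_real_, p_r = NA_real_, n_pairs = sum(ok),
                      iqr_run1 = stats::IQR(x, na.rm = TRUE, type = 7),
                      flag = "ok", stringsAsFactors = FALSE)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      rec$flag <- if (sum(ok) < 3) "too_few_pairs" else "degenerate"
      return(rec)
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    rec$r <- unname(ct$estimate)
    rec$p_r <- ct$p.value
    rec
  })
  out <- do.call(rbind, res)
  attr(out, "mean_r") <- mean(out$r, na.rm = TRUE)
  attr(out, "frac_above_0.7") <- mean(out$r > 0.7, na.rm = TRUE)
  out
}

#' Does biological spread track reproducibility?
#'
#' Pearson correlation between each analyte's IQR in the first run and its
#' cross-run correlation: under a constant-technical-noise model, analytes
#' with larger biological spread attenuate less and reproduce better, so a
#' positive correlation is expected.
#'
#' @param records Output of [paired_correlations()] (>= 10 analytes with a
#'   reported `r`).
#' @return A list: `r`, `p`, `n`, `flag` (`"ok"` or `"degenerate"` when
#'   either variable has no variance).
#' @export
iqr_vs_reproducibility <- function(records) {
  ok <- !is.na(records$r) & !is.na(records$iqr_run1)
  if (sum(ok) < 10) stopf("need >= 10 analytes with a reported correlation")
  x <- records$iqr_run1[ok]
  y <- records$r[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = sum(ok), flag = "degenerate"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), flag = "ok")
}
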