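#' Confusion-matrix summary between predicted and reference status
#'
#' 2x2 counts and derived metrics for a binary prediction against a binary
#' reference, with support for trichotomous (low/intermediate/high)
#' predictions from the dual-cutoff scheme: intermediates are counted and
#' excluded from the 2x2 table when `drop_intermediate = TRUE` (the
#' convention for dual-cutoff concordance), and are an error otherwise.
#' Pairs with a missing prediction or reference are excluded. The
#' concordance percentage is rounded half-up to two decimals, matching the
#' usual printed precision.
#'
#' @param pred Logical vector, or factor/character with levels
#'   low/intermediate/high (low maps to negative, high to positive).
#' @param ref Logical reference status, same length.
#' @param drop_intermediate Drop intermediate-class samples before counting?
#' @return A `confusion_summary`; see [confusion_from_counts()].
#' @export
confusion <- function(pred, ref, drop_intermediate = FALSE) {
  if (length(pred) != length(ref)) {
    stopf("pred and ref have different lengths (%d vs %d)",
          length(pred), length(ref))
  }
  n_intermediate <- 0L
  if (!is.logical(pred)) {
    cls <- as.character(pred)
    bad <- !is.na(cls) & !cls %in% c("low", "intermediate", "high")
    if (any(bad)) stopf("unknown class label(s): %s",
                        paste(unique(cls[bad]), collapse = ", "))
    inter <- !is.na(cls) & cls == "intermediate"
    n_intermediate <- sum(inter & !is.na(ref))
    if (any(inter) && !drop_intermediate) {
      stopf("intermediate classes present; call with drop_intermediate = TRUE")
    }
    pred <- ifelse(inter, NA, cls == "high")
  }
  keep <- !is.na(pred) & !is.na(ref)
  pred <- pred[keep]
  ref <- as.logical(ref[keep])
  confusion_from_counts(tp = sum(pred & ref), fp = sum(pred & !ref),
                        tn = sum(!pred & !ref), fn = sum(!pred & ref),
                        n_intermediate = n_intermediate)
}

#' Confusion summary from counts
#'
#' Builds the metric set directly from 2x2 counts (e.g. printed confusion
#' tables): concordance percentage (half-up, 2 decimals), sensitivity,
#' specificity, PPV and NPV. Metrics with an empty denominator are `NA` and
#' flagged.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @param n_intermediate Samples excluded as intermediate (informational).
#' @return A list of class `confusion_summary`.
#' @examples
#' confusion_from_counts(tp = 1443, fp = 12, tn = 2093, fn = 14)
#' @export
confusion_from_counts <- function(tp, fp, tn, fn, n_intermediate = 0L) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  if (n == 0) stopf("empty confusion table")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    n_intermediate = as.integer(n_intermediate),
    concordance_pct = round_half_up(100 * (tp + tn) / n, 2),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    undefined = c(ppv = tp + fp == 0, npv = tn + fn == 0,
                  sensitivity = tp + fn == 0, specificity = tn + fp == 0)
  ), class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("confusion: tp %d fp %d tn %d fn %d (n = %d%s)\n",
              x$tp, x$fp, x$tn, x$fn, x$n,
              if (x$n_intermediate > 0)
                sprintf(", %d intermediate excluded", x$n_intermediate)
              else ""))
  cat(sprintf("  concordance %.2f%%; sens %.3f spec %.3f ppv %.3f npv %.3f\n",
              x$concordance_pct, x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

#' Concordance percentage from agreement counts
#'
#' @param n_concordant,n_total Counts with `n_concordant <= n_total`.
#' @return Percentage agreement rounded half-up to two decimals.
#' @examples
#' concordance_rate(3197, 3222) # 99.22
#' @export
concordance_rate <- function(n_concordant, n_total) {
  stopifnot(n_total > 0, n_concordant >= 0, n_concordant <= n_total)
  round_half_up(100 * n_concordant / n_total, 2)
}

#' APOE epsilon-4 carrier status from the proteoform assay
#'
#' Classifies samples as epsilon-4 carriers from the APOE e4
#' proteoform-specific analyte: a two-component mixture cutoff
#' ([gmm_cutoff()]) is fit to the analyte's log10 values and samples above
#' the equal-posterior cutoff are called carriers. The mixture's
#' low-confidence flag (overlapping modes, e.g. no proteoform signal)
#' propagates as an attribute.
#'
#' @param m An [npq_matrix()] on the log10 scale.
#' @param apoe_analyte Analyte ID of the proteoform assay (default
#'   `"APOE4"`).
#' @param ... Passed to [gmm_cutoff()].
#' @return Named logical vector (carrier = `TRUE`) with attributes `model`
#'   (the `mixture_cutoff_model`) and `low_confidence`.
#' @export
classify_apoe4_from_proteoform <- function(m, apoe_analyte = "APOE4", ...) {
  stopifnot(inherits(m, "npq_matrix"))
  if (npq_scale(m) != "log10") {
    stopf("expected a log10-scale matrix; use transform_scale()")
  }
  if (!apoe_analyte %in% colnames(m)) {
    stopf("analyte %s not in matrix", apoe_analyte)
  }
  x <- m[, apoe_analyte]
  model <- gmm_cutoff(x[is.finite(x)], ...)
  out <- x > model$cutoff_log10
  names(out) <- rownames(m)
  attr(out, "model") <- model
  attr(out, "low_confidence") <- model$low_confidence
  out
}

#' APOE4 status from genotype
#'
#' Maps the six APOE genotypes to carrier status: e2/e2, e2/e3 and e3/e3
#' are APOE4-negative; e2/e4, e3/e4 and e4/e4 are APOE4-positive. Both
#' ASCII (`"e3/e4"`) and epsilon (`"ε3/ε4"`) spellings are
#' accepted; missing genotypes stay missing; any other string is an error.
#'
#' @param apoe_genotype Character vector of genotypes.
#' @return Logical vector (`TRUE` = carrier).
#' @examples
#' genotype_to_apoe4(c("e3/e3", "e2/e4", NA))
#' @export
genotype_to_apoe4 <- function(apoe_genotype) {
  g <- tolower(gsub("ε", "e", as.character(apoe_genotype)))
  map <- c("e2/e2" = FALSE, "e2/e3" = FALSE, "e3/e3" = FALSE,
           "e2/e4" = TRUE, "e3/e4" = TRUE, "e4/e4" = TRUE)
  bad <- !is.na(g) & !g %in% names(map)
  if (any(bad)) {
    stopf("unknown APOE genotype: %s", paste(unique(g[bad]), collapse = ", "))
  }
  unname(map[g])
}
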