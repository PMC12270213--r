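#' Samples-by-analytes NPQ matrix
#'
#' Container for targeted-proteomics measurements in normalized protein
#' quantification (NPQ) units. Rows are samples, columns are analytes, and a
#' scale tag records whether values are stored as log2, linear, or log10 NPQ.
#' NPQ is natively log2; linear values are obtained by exponentiation and are
#' strictly positive wherever observed.
#'
#' @param values Numeric matrix (samples in rows, analytes in columns) with
#'   unique, non-empty row and column names. `NA` marks missing measurements.
#' @param scale One of `"log2"`, `"linear"`, `"log10"`.
#' @return An object of class `npq_matrix`: the numeric matrix with a
#'   `scale` attribute.
#' @examples
#' m <- npq_matrix(matrix(rnorm(6, 10), 3, 2,
#'                        dimnames = list(paste0("S", 1:3), c("A", "B"))),
#'                 scale = "log2")
#' npq_scale(m)
#' @export
npq_matrix <- function(values, scale = c("log2", "linear", "log10")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  sid <- rownames(values)
  aid <- colnames(values)
  if (is.null(sid) || is.null(aid) || any(!nzchar(sid)) || any(!nzchar(aid))) {
    stopf("`values` must have non-empty row (sample) and column (analyte) names")
  }
  if (anyDuplicated(sid)) {
    stopf("duplicate sample ID: %s", sid[duplicated(sid)][1])
  }
  if (anyDuplicated(aid)) {
    stopf("duplicate analyte ID: %s", aid[duplicated(aid)][1])
  }
  if (scale == "linear") check_positive_linear(values)
  structure(values, scale = scale, class = c("npq_matrix", "matrix", "array"))
}

check_positive_linear <- function(values) {
  bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 5), 1, function(ij) {
      paste0("[", rownames(values)[ij[1]], ", ", colnames(values)[ij[2]], "]")
    })
    stopf("linear-scale NPQ values must be positive; offending cell(s): %s%s",
          paste(cells, collapse = ", "),
          if (nrow(bad) > 5) sprintf(" and %d more", nrow(bad) - 5) else "")
  }
  invisible(TRUE)
}

#' @rdname npq_matrix
#' @param m An `npq_matrix`.
#' @export
npq_scale <- function(m) {
  stopifnot(inherits(m, "npq_matrix"))
  attr(m, "scale")
}

#' @export
print.npq_matrix <- function(x, ...) {
  cat(sprintf("npq_matrix: %d samples x %d analytes (%s scale), %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "scale"), 100 * mean(is.na(x))))
  invisible(x)
}

#' Convert an NPQ matrix between scales
#'
#' Element-wise scale conversion: `2^x` takes log2 to linear, `log10(x)`
#' takes linear to log10, and log-to-log conversions use the exact change of
#' base `log10 = log2 * log10(2)`. Missing entries stay missing. Converting
#' linear values to a log scale requires all observed values to be positive.
#'
#' @param m An [npq_matrix()].
#' @param target Target scale: `"log2"`, `"linear"`, or `"log10"`.
#' @return An `npq_matrix` on the target scale, same dimensions and names.
#' @examples
#' m <- npq_matrix(matrix(4582.42, 1, 1, dimnames = list("S1", "pTau217")),
#'                 scale = "linear")
#' transform_scale(m, "log10")[1, 1] # 3.661...
#' @export
transform_scale <- function(m, target = c("log2", "linear", "log10")) {
  target <- match.arg(target)
  stopifnot(inherits(m, "npq_matrix"))
  from <- attr(m, "scale")
  if (from == target) return(m)
  v <- unclass(m)
  attr(v, "scale") <- NULL
  if (from == "linear") check_positive_linear(v)
  out <- switch(paste(from, target, sep = "->"),
    "log2->linear"  = 2^v,
    "log10->linear" = 10^v,
    "linear->log2"  = log2(v),
    "linear->log10" = log10(v),
    "log2->log10"   = v * log10(2),
    "log10->log2"   = v / log10(2)
  )
  npq_matrix(out, scale = target)
}

#' Read an NPQ matrix from a delimited text file
#'
#' Expects a header row of analyte IDs with the first column holding sample
#' IDs. The delimiter is taken from the file extension: comma for `.csv`,
#' tab otherwise. The tokens `""`, `"NA"`, `"NaN"`, `"nan"` are read as
#' missing. Duplicate sample or analyte IDs and non-numeric cells are hard
#' errors that name the offending ID or cell.
#'
#' @param path Path to a TSV/CSV file.
#' @param scale Scale tag to attach to the values (the file does not encode
#'   it); one of `"log2"`, `"linear"`, `"log10"`.
#' @return An [npq_matrix()] preserving file row/column order.
#' @seealso [write_npq_matrix()]
#' @export
read_npq_matrix <- function(path, scale = c("log2", "linear", "log10")) {
  scale <- match.arg(scale)
  sep <- delim_for(path)
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", na.strings = character(0))
  if (nrow(raw) < 2 || ncol(raw) < 2) stopf("file %s has no data cells", path)
  aid <- as.character(raw[1, -1])
  sid <- as.character(raw[-1, 1])
  if (anyDuplicated(aid)) {
    stopf("duplicate analyte ID in header of %s: %s",
          path, aid[duplicated(aid)][1])
  }
  if (anyDuplicated(sid)) {
    stopf("duplicate sample ID in %s: %s", path, sid[duplicated(sid)][1])
  }
  cells <- as.matrix(raw[-1, -1, drop = FALSE])
  miss <- is.na(cells) | cells %in% c("", "NA", "NaN", "nan")
  num <- suppressWarnings(as.numeric(cells))
  bad <- which(matrix(!miss & is.na(num), nrow = length(sid)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stopf("non-numeric cell in %s at sample '%s', analyte '%s': '%s'",
          path, sid[i], aid[j], cells[i, j])
  }
  num[miss] <- NA_real_
  values <- matrix(num, nrow = length(sid), ncol = length(aid),
                   dimnames = list(sid, aid))
  npq_matrix(values, scale = scale)
}

#' Write an NPQ matrix to a delimited text file
#'
#' Inverse of [read_npq_matrix()]: sample IDs in the first column (header
#' `sample_id`), analyte IDs in the header row, missing values written as
#' `NA`. Numbers are written with `%.17g` so that read-back reproduces the
#' stored doubles exactly.
#'
#' @param m An [npq_matrix()].
#' @param path Output path; `.csv` selects comma, anything else tab.
#' @return `path`, invisibly.
#' @export
write_npq_matrix <- function(m, path) {
  stopifnot(inherits(m, "npq_matrix"))
  sep <- delim_for(path)
  cells <- matrix(fmt_num(m), nrow = nrow(m))
  lines <- c(
    paste(c("sample_id", colnames(m)), collapse = sep),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], cells[i, ]), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a result table as delimited text
#'
#' Deterministic serialization for association, QC, survival, and
#' reproducibility tables: columns in their existing order, numeric columns
#' written with full (`%.17g`) precision, missing values as `NA`, no quoting
#' or row names. Writing then re-reading then re-writing reproduces the file
#' byte for byte.
#'
#' @param records A data.frame.
#' @param path Output path; `.csv` selects comma, anything else tab.
#' @param allow_empty Permit a zero-row table (header-only file)?
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, allow_empty = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0 && !allow_empty) {
    stopf("refusing to write empty table %s (use allow_empty = TRUE)", path)
  }
  sep <- delim_for(path)
  cols <- lapply(records, function(col) {
    if (is.numeric(col) && !is.integer(col)) fmt_num(col)
    else {
      out <- as.character(col)
      out[is.na(out)] <- "NA"
      out
    }
  })
  body <- if (nrow(records) == 0) character(0) else do.call(paste, c(cols, sep = sep))
  writeLines(c(paste(names(records), collapse = sep), body), path)
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path Path to a TSV/CSV file.
#' @return A data.frame with numeric columns restored where every non-missing
#'   entry parses as a number.
#' @export
read_result_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", na.strings = c("NA", ""))
  df[] <- lapply(df, function(col) {
    num <- suppressWarnings(as.numeric(col))
    if (all(is.na(col) == is.na(num))) num else col
  })
  df
}
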