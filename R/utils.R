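# Internal helpers shared across the pipeline.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up in absolute value
#' (0.005 -> 0.01), the convention used for printed concordance percentages.
#' Base `round()` rounds half to even, which differs on exact ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Male indicator used in all adjusted models: sex coded {"male","female"}.
male_indicator <- function(sex) {
  s <- tolower(as.character(sex))
  bad <- !is.na(s) & !s %in% c("male", "female")
  if (any(bad)) {
    stopf("unrecognized sex value(s): %s",
          paste(unique(s[bad]), collapse = ", "))
  }
  as.integer(s == "male")
}
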