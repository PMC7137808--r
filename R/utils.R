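# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published epidemiological tables are
#' conventionally rounded half-up, so percentages such as 6.25 print as 6.3.
#' A small epsilon guards against decimal fractions that are not exactly
#' representable in binary.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' Format a count as a one-decimal percentage
#'
#' @param num numerator count.
#' @param den denominator count; a zero denominator yields `NA` (an empty
#'   cell in rendered tables).
#' @param digits decimal places (default 1, the convention of the report
#'   tables).
#' @return numeric vector of rounded percentages.
#' @examples
#' format_percent(212, 2973)  # 7.1
#' @export
format_percent <- function(num, den, digits = 1) {
  len <- max(length(num), length(den))
  num <- rep_len(num, len)
  den <- rep_len(den, len)
  ifelse(is.na(den) | den == 0, NA_real_,
         round_half_up(100 * num / den, digits))
}

# Quantile with the package-wide default rule (linear interpolation between
# order statistics, stats type 7).  Exposed as an argument everywhere the
# published cutoffs could depend on it.
pf_quantile <- function(x, probs, type = 7) {
  stats::quantile(x, probs = probs, na.rm = TRUE, names = FALSE, type = type)
}

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stopifnot with a formatted message
pf_assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
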