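#' Percentage of a count, rounded for tabulation
#'
#' Small helper used throughout descriptive reports: the percentage
#' \code{100 * x / n}, rounded to one decimal place as conventionally
#' printed in epidemiologic baseline tables.
#'
#' @param x numerator count.
#' @param n denominator count, > 0.
#' @param digits decimal places to keep (default 1).
#' @return numeric percentage.
#' @examples
#' pct(1183, 1852)  # 63.9
#' @export
pct <- function(x, n, digits = 1) {
  stopifnot(is.numeric(x), is.numeric(n), all(n > 0))
  round(100 * x / n, digits)
}

# internal: derive a reproducible 32-bit sub-seed from a master seed and a
# stage label, so each pipeline stage gets its own stream.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# internal: stop() with a message assembled sprintf-style
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
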