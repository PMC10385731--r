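# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves moving away from zero
#' (so 0.05 -> 0.1 and -0.05 -> -0.1), the convention used for the
#' percent-change figures this package reports. Base [round()] uses
#' banker's rounding and would map 8.05 to 8.0.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(c(0.05, -0.05, 12.649), 1)
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a distinct child seed from a parent seed, staying inside the
# 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + 7919L * as.double(k)) %% 2147483647)
}

stop_itgrow <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "itgrow_error")))
}
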