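#' Round half away from zero
#'
#' Display rounding used throughout the report tables: exact halves round
#' away from zero (so 2.05 -> 2.1), unlike [base::round()]'s round-half-even.
#' Clinical tables conventionally use this rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the display precision
#'   for doses and radii).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(5.766)   # 5.8
#' round_half_up(2.05)    # 2.1
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert day counts to months
#'
#' Uses the fixed 30 days/month convention, the only one consistent with
#' paired day/month values such as 642 d = 21.4 mo and 173 d = 5.8 mo.
#'
#' @param days Numeric vector of day counts.
#' @param digits Decimal places for the reported month value.
#' @return Months, rounded half-up.
#' @export
#' @examples
#' days_to_months(642)  # 21.4
#' days_to_months(173)  # 5.8
days_to_months <- function(days, digits = 1) {
  round_half_up(days / 30, digits)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# stop() with a consistent condition class so callers can distinguish
# validation failures (the CLI maps these to exit code 2)
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("reirrad_validation_error", "error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
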