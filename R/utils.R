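#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Linear-congruential mixing of a master seed with a stream index, kept
#' within the 32-bit signed integer range so the result is always a valid
#' argument to [set.seed()]. Used throughout the package so that population
#' generation, disease allocation, pathway draws and PSA runs each consume
#' an independent, reproducible stream.
#'
#' @param master integer master seed.
#' @param index integer stream/run index (>= 0).
#' @param stream optional extra offset distinguishing named sub-streams.
#' @return a single integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(master, index = 0L, stream = 0L) {
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.numeric(master) %% m)
  x <- (x * 48271 + as.numeric(index) * 16807 + as.numeric(stream) * 69621 + 1) %% m
  as.integer(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("'%s' must lie in [0, 1]", name)
  invisible(x)
}

#' Discount a future amount to present value
#'
#' Annual-convention discounting: an amount accrued `years_from_baseline`
#' years after model start is divided by `(1 + rate)^floor(years)`. Year-0
#' accruals are undiscounted, matching the cycle-start accrual convention of
#' the lifetime model.
#'
#' @param amount numeric amount (cost in GBP or QALYs).
#' @param years_from_baseline non-negative years since model start.
#' @param rate annual discount rate (default 0.035).
#' @return discounted amount.
#' @examples
#' discount(100, 1, 0.035)  # 96.618...
#' @export
discount <- function(amount, years_from_baseline, rate = 0.035) {
  if (any(rate < 0)) stopf("discount rate must be >= 0")
  if (any(years_from_baseline < 0)) stopf("years_from_baseline must be >= 0")
  amount / (1 + rate)^floor(years_from_baseline)
}
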