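#' @importFrom rlang .data abort
#' @importFrom stats rnorm runif rexp rpois rbinom qnorm pnorm sd median
NULL

# Follow-up day convention used throughout: day 1 is the index date itself,
# day 365 the last follow-up day.
follow_up_day <- function(date, index_date) {
  as.integer(date - index_date) + 1L
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used for the printed percentages in patient-flow and characteristics
#' tables), unlike base [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop with a classed condition so tests can assert on error class
stop_ss <- function(msg, class) {
  rlang::abort(msg, class = c(class, "switchsignal_error"))
}
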