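#' Round half away from zero
#'
#' Report tables use commercial ("half-up") rounding, e.g. 65.625 -> 65.63,
#' rather than the IEEE round-half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(65.625, 2)  # 65.63, where round() gives 65.62
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # 1e-9 guard: values such as 65.625 are stored fractionally below the
  # true tie point; without it the half-up rule would misfire on exact ties.
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf-style formatting, no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
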