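#' Round half away from zero
#'
#' Rounds to a fixed number of decimal places with the "half up" rule used
#' on clinical report forms, so that e.g. 38.05 becomes 38.1.  Base R's
#' `round()` rounds half to even, which would report 38.0 instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(100 * 16 / 42, 1)  # 38.1
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# points on the instrument are exact multiples of 0.5; snap away float noise
is_half_step <- function(x, tol = 1e-9) {
  abs(x * 2 - round(x * 2)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_with <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "marepain_error")))
}

warn_with <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...), class = c(class, "marepain_warning")))
}
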