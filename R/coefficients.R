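#' Growth-law coefficients
#'
#' Constructs the pair of global slope coefficients of the log-quadratic
#' neonatal growth law \eqn{P = P_0 \exp(b_1 x - b_2 x^2)}, where \eqn{x}
#' is age in days and \eqn{P} weight in grams. `b1` (day^-1) sets the
#' initial relative growth rate; `b2` (day^-2) the linear deceleration of
#' that rate with age. Both are stored positive, with the minus sign
#' living in the model exponent, so there is no sign ambiguity between
#' the growth law and its derivative.
#'
#' @param b1 Growth-rate coefficient, per day. Must be > 0.
#' @param b2 Deceleration coefficient, per day squared. Must be >= 0.
#' @return An object of class `growth_coefficients`: a list with fields
#'   `b1` and `b2`.
#' @examples
#' growth_coefficients()          # published reference values
#' growth_coefficients(0.12, 0.001)
#' @export
growth_coefficients <- function(b1 = 0.13084, b2 = 0.001616) {
  if (!is.numeric(b1) || length(b1) != 1L || !is.finite(b1) || b1 <= 0) {
    stop("`b1` must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(b2) || length(b2) != 1L || !is.finite(b2) || b2 < 0) {
    stop("`b2` must be a single non-negative finite number", call. = FALSE)
  }
  structure(list(b1 = as.numeric(b1), b2 = as.numeric(b2)),
            class = "growth_coefficients")
}

#' @export
print.growth_coefficients <- function(x, ...) {
  cat("Log-quadratic growth coefficients\n")
  cat(sprintf("  b1 = %.6g /day,  b2 = %.6g /day^2\n", x$b1, x$b2))
  if (x$b2 > 0) {
    cat(sprintf("  relative daily gain: %.1f%% (day 0) -> %.1f%% (day 21)\n",
                100 * x$b1, 100 * (x$b1 - 2 * x$b2 * 21)))
  }
  invisible(x)
}

as_growth_coefficients <- function(coeffs) {
  if (inherits(coeffs, "growth_coefficients")) return(coeffs)
  if (is.numeric(coeffs) && length(coeffs) == 2L) {
    return(growth_coefficients(coeffs[[1L]], coeffs[[2L]]))
  }
  if (is.list(coeffs) && all(c("b1", "b2") %in% names(coeffs))) {
    return(growth_coefficients(coeffs$b1, coeffs$b2))
  }
  stop("`coeffs` must be a growth_coefficients object or a (b1, b2) pair",
       call. = FALSE)
}

# Largest day shown in published monitoring data; beyond it the quadratic
# exponent is extrapolation (its vertex near day 40 is an artifact).
.max_supported_day <- 28

warn_if_extrapolating <- function(day) {
  if (any(day > .max_supported_day)) {
    warning(sprintf(
      "day > %d lies beyond the model's supported neonatal window; %s",
      .max_supported_day,
      "treat predictions as extrapolation"), call. = FALSE)
  }
  invisible(NULL)
}
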