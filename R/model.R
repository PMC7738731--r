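# Closed-form growth law and every quantity derived from it.
# Weight on day x for a curve anchored at p0 grams on day 0:
#   P(x) = p0 * exp(b1*x - b2*x^2)

growth_factor <- function(day, coeffs) {
  exp(coeffs$b1 * day - coeffs$b2 * day^2)
}

check_day <- function(day, arg = "day") {
  if (!is.numeric(day) || any(!is.finite(day)) || any(day < 0)) {
    stop(sprintf("`%s` must be non-negative and finite", arg), call. = FALSE)
  }
  invisible(NULL)
}

check_p0 <- function(p0_g, arg = "p0_g") {
  if (!is.numeric(p0_g) || length(p0_g) == 0L ||
      any(!is.finite(p0_g)) || any(p0_g <= 0)) {
    stop(sprintf("`%s` must be positive and finite", arg), call. = FALSE)
  }
  invisible(NULL)
}

#' Predicted weight on a growth curve
#'
#' Evaluates the log-quadratic growth law
#' \eqn{P(x) = P_0 \exp(b_1 x - b_2 x^2)} for a curve anchored at
#' `p0_g` grams on day 0. Day is real-valued; both arguments vectorise.
#' Days beyond the supported neonatal window (28 d) trigger a warning,
#' since the quadratic exponent is not meant for extrapolation.
#'
#' @param p0_g Day-0 weight of the curve, grams (> 0).
#' @param day Age in days since birth (>= 0).
#' @param coeffs A [growth_coefficients()] object; defaults to the
#'   published values.
#' @return Predicted weight in grams.
#' @examples
#' predict_weight(100, 0)         # exactly 100
#' predict_weight(250, 21)        # about 1913 g
#' @export
predict_weight <- function(p0_g, day, coeffs = growth_coefficients()) {
  coeffs <- as_growth_coefficients(coeffs)
  check_p0(p0_g)
  check_day(day)
  warn_if_extrapolating(day)
  p0_g * growth_factor(day, coeffs)
}

#' Absolute daily weight gain
#'
#' First derivative of the growth law with respect to age:
#' \eqn{dP/dx = P(x)\,(b_1 - 2 b_2 x)} grams per day. It is proportional
#' to current weight, which is why heavier puppies diverge from lighter
#' littermates in absolute terms while sharing the same relative rate.
#'
#' @inheritParams predict_weight
#' @return Gain in grams per day.
#' @export
daily_gain <- function(p0_g, day, coeffs = growth_coefficients()) {
  coeffs <- as_growth_coefficients(coeffs)
  check_p0(p0_g)
  check_day(day)
  warn_if_extrapolating(day)
  predict_weight(p0_g, day, coeffs) * (coeffs$b1 - 2 * coeffs$b2 * day)
}

#' Relative daily weight gain
#'
#' \eqn{(dP/dx)/P = b_1 - 2 b_2 x}: independent of the puppy's weight,
#' linearly decreasing with age. With the published coefficients it runs
#' from 13.1%/day at birth to 6.3%/day at day 21.
#'
#' @inheritParams predict_weight
#' @return Fractional gain per day (0.131 means 13.1%/day).
#' @export
relative_daily_gain <- function(day, coeffs = growth_coefficients()) {
  coeffs <- as_growth_coefficients(coeffs)
  check_day(day)
  coeffs$b1 - 2 * coeffs$b2 * day
}

#' Mean relative daily gain over an age interval
#'
#' Closed-form average of [relative_daily_gain()] over
#' `[day_start, day_end]`: since the integrand is linear, the mean is
#' \eqn{b_1 - b_2 (x_s + x_e)}. Over days 0–21 with the published
#' coefficients this is 0.097, i.e. roughly 10%/day.
#'
#' @param day_start,day_end Interval bounds in days, `0 <= day_start <
#'   day_end`.
#' @inheritParams predict_weight
#' @return Fractional gain per day.
#' @export
mean_relative_daily_gain <- function(day_start, day_end,
                                     coeffs = growth_coefficients()) {
  coeffs <- as_growth_coefficients(coeffs)
  check_day(day_start, "day_start")
  check_day(day_end, "day_end")
  if (any(day_end <= day_start)) {
    stop("`day_start` must be strictly less than `day_end`", call. = FALSE)
  }
  coeffs$b1 - coeffs$b2 * (day_start + day_end)
}

#' Time to reach a weight multiple
#'
#' Solves \eqn{\exp(b_1 x - b_2 x^2) = m / s} for the first crossing,
#' i.e. the smallest non-negative root of
#' \eqn{b_2 x^2 - b_1 x + \ln(m/s) = 0}. `start_ratio` (s) is the P0 of
#' the curve the puppy currently follows divided by its birth weight, so
#' doubling time after a setback is `time_to_multiple(2, start_ratio =
#' setback_adjusted_p0(...))`. The smaller quadratic root is returned:
#' the larger one lies past the vertex (~day 40), outside the model's
#' validity. Doubling from birth on the birth-weight curve takes 5.7
#' days with the published coefficients.
#'
#' @param multiple Target weight as a multiple of birth weight (> 0).
#' @param start_ratio P0 of the current curve over birth weight (> 0,
#'   default 1: never fell off the birth-weight curve).
#' @inheritParams predict_weight
#' @return Days until the target is reached; 0 when already at or above
#'   it.
#' @examples
#' time_to_multiple(2)                      # 5.7 days
#' time_to_multiple(2, start_ratio = 0.62)  # ~10.3 days after a 20% setback
#' @export
time_to_multiple <- function(multiple, coeffs = growth_coefficients(),
                             start_ratio = 1) {
  coeffs <- as_growth_coefficients(coeffs)
  if (!is.numeric(multiple) || any(multiple <= 0)) {
    stop("`multiple` must be positive", call. = FALSE)
  }
  if (!is.numeric(start_ratio) || any(start_ratio <= 0)) {
    stop("`start_ratio` must be positive", call. = FALSE)
  }
  target <- log(multiple / start_ratio)
  out <- numeric(length(target))
  for (i in seq_along(target)) {
    ti <- target[i]
    if (ti <= 0) {
      out[i] <- 0
      next
    }
    if (coeffs$b2 == 0) {
      out[i] <- ti / coeffs$b1
      next
    }
    disc <- coeffs$b1^2 - 4 * coeffs$b2 * ti
    if (disc < 0) {
      stop(sprintf(
        "target multiple %.4g exceeds the curve maximum exp(b1^2/(4*b2)) = %.4g",
        multiple[min(i, length(multiple))], exp(coeffs$b1^2 / (4 * coeffs$b2))),
        call. = FALSE)
    }
    out[i] <- (coeffs$b1 - sqrt(disc)) / (2 * coeffs$b2)
  }
  out
}

#' Curve offset after an early setback
#'
#' A puppy that stagnates or loses weight in its first days later joins
#' a curve lower than its birth-weight curve. If at day `at_day` the
#' puppy weighs `retained_fraction` of its birth weight, the curve
#' through that point has day-0 value
#' \eqn{P_0' / P_0 = f / \exp(b_1 t - b_2 t^2)}. The returned value is
#' that ratio (dimensionless): multiply by birth weight for grams.
#'
#' Example scenarios: no gain in the first 24 h gives ratio 0.879; a 20%
#' loss over the first 48 h gives 0.620.
#'
#' @param retained_fraction Weight at `at_day` over birth weight, in
#'   (0, 1].
#' @param at_day Day at which that weight is observed (>= 0).
#' @inheritParams predict_weight
#' @return New P0 as a fraction of birth weight.
#' @export
setback_adjusted_p0 <- function(retained_fraction, at_day,
                                coeffs = growth_coefficients()) {
  coeffs <- as_growth_coefficients(coeffs)
  if (!is.numeric(retained_fraction) ||
      any(retained_fraction <= 0) || any(retained_fraction > 1)) {
    stop("`retained_fraction` must lie in (0, 1]", call. = FALSE)
  }
  check_day(at_day, "at_day")
  retained_fraction / growth_factor(at_day, coeffs)
}

#' Growth-chart table
#'
#' Tabulates model curves for a set of day-0 weights over an integer day
#' grid, the tabular analogue of a printed growth chart: one row per
#' day, one column per curve. The day-0 row reproduces `p0_values`
#' exactly and every column is strictly increasing over the neonatal
#' window.
#'
#' @param p0_values Day-0 weights of the curves to chart, grams.
#' @param day_start,day_end Integer day range (inclusive), default 0–21.
#' @inheritParams predict_weight
#' @return A data.frame with integer column `day` and one column
#'   `p0_<grams>` per requested curve.
#' @examples
#' head(growth_chart_table(c(100, 250, 400)))
#' @export
growth_chart_table <- function(p0_values, day_start = 0, day_end = 21,
                               coeffs = growth_coefficients()) {
  coeffs <- as_growth_coefficients(coeffs)
  if (length(p0_values) == 0L) {
    stop("`p0_values` must contain at least one day-0 weight", call. = FALSE)
  }
  check_p0(p0_values, "p0_values")
  check_day(day_start, "day_start")
  check_day(day_end, "day_end")
  if (day_end < day_start) {
    stop("`day_end` must be >= `day_start`", call. = FALSE)
  }
  warn_if_extrapolating(day_end)
  days <- seq(as.integer(day_start), as.integer(day_end))
  chart <- data.frame(day = days)
  g <- growth_factor(days, coeffs)
  for (p0 in p0_values) {
    chart[[sprintf("p0_%g", p0)]] <- p0 * g
  }
  chart
}

#' Export a growth chart as CSV
#'
#' Writes [growth_chart_table()] output with weights rounded to one
#' decimal gram for display; the first column is the integer day.
#'
#' @param chart A data.frame from [growth_chart_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_chart <- function(chart, path) {
  stopifnot(is.data.frame(chart), names(chart)[1L] == "day")
  out <- chart
  for (j in seq_along(out)[-1L]) out[[j]] <- round(out[[j]], 1)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a growth chart
#'
#' Draws the model curves of a growth-chart table on either the natural
#' or the logarithmic weight scale (curves for different P0 are parallel
#' in log scale).
#'
#' @param chart A data.frame from [growth_chart_table()].
#' @param log_scale Plot ln-weight instead of grams.
#' @param ... Passed to [graphics::matplot()].
#' @return The chart, invisibly.
#' @export
plot_growth_chart <- function(chart, log_scale = FALSE, ...) {
  stopifnot(is.data.frame(chart), names(chart)[1L] == "day")
  w <- as.matrix(chart[, -1L, drop = FALSE])
  graphics::matplot(chart$day, w, type = "l", lty = 1,
                    log = if (log_scale) "y" else "",
                    xlab = "age, days", ylab = "weight, g", ...)
  graphics::legend("topleft", legend = colnames(w), lty = 1,
                   col = seq_len(ncol(w)), bty = "n", cex = 0.8)
  invisible(chart)
}
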