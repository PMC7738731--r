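# Pipeline entry points tying the modules together: each run_* function
# is a pure function of (inputs, config, seed) usable from R or from
# the thin command-line wrapper in inst/cli/pupgrowth.R. Fit reports
# are JSON with fixed key names so they can be consumed by other tools.

log_msg <- function(...) {
  message(sprintf(...))
}

#' Simulate a dataset and write it to CSV
#'
#' @param out_path Output CSV path.
#' @param config A [sim_config()].
#' @param seed Integer seed (overrides `config$seed`).
#' @return The dataset (invisibly); the CSV is written to `out_path`.
#' @export
run_simulate <- function(out_path, config = sim_config(), seed = NULL) {
  ds <- simulate_population(config, seed = seed)
  export_dataset(ds$records, out_path)
  log_msg("wrote %d records for %d puppies to %s",
          nrow(ds$records), length(ds$truth), out_path)
  invisible(ds)
}

#' Fit the global growth coefficients from a dataset file
#'
#' Loads a weight-record CSV, selects the polynomial order and fits the
#' shared-slope log regression; optionally writes a JSON report with
#' keys `order, coeffs.b1, coeffs.b2, r2, adj_r2, resid_se,
#' intercepts.<puppy_id>`.
#'
#' @param data_path Input CSV (see [load_dataset()]).
#' @param max_order Largest polynomial order tried.
#' @param day_window Inclusive age window used for fitting.
#' @param report_path Optional JSON report path.
#' @return The selected `global_fit`.
#' @export
run_fit_global <- function(data_path, max_order = 4, day_window = c(0, 28),
                           report_path = NULL) {
  records <- load_dataset(data_path)
  fit <- select_order(records, max_order = max_order, day_window = day_window)
  log_msg("selected order %d: R2 = %.4f, adj R2 = %.4f, resid SE = %.4g",
          fit$order, fit$r2, fit$adj_r2, fit$resid_se)
  if (!is.null(report_path)) {
    write_fit_report(fit, report_path)
  }
  fit
}

#' Write a global-fit JSON report
#'
#' @param fit A `global_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "global_fit"))
  slopes <- fit$coefficients$estimate
  report <- list(
    order = fit$order,
    coeffs = list(b1 = slopes[1L],
                  b2 = if (fit$order >= 2L) -slopes[2L] else 0),
    slope_terms = stats::setNames(as.list(slopes), fit$coefficients$term),
    r2 = fit$r2, adj_r2 = fit$adj_r2, resid_se = fit$resid_se,
    n_obs = fit$n_obs,
    intercepts = stats::setNames(as.list(fit$intercepts$a),
                                 fit$intercepts$puppy_id))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Segment every puppy in a dataset file
#'
#' Loads a weight-record CSV and fits per-puppy trajectories against
#' either the published coefficients or coefficients taken from a fit
#' report produced by [run_fit_global()].
#'
#' @param data_path Input CSV.
#' @param coeffs_source `"published"` (default) or the path of a JSON
#'   fit report.
#' @param drop_threshold,min_run,min_seg_len Passed to
#'   [segment_trajectory()].
#' @return A list: `trajectories` (per puppy), `summary`
#'   ([population_summary()] output), `coeffs`.
#' @export
run_fit_trajectories <- function(data_path, coeffs_source = "published",
                                 drop_threshold = 0.03, min_run = 2,
                                 min_seg_len = 2) {
  records <- load_dataset(data_path)
  coeffs <- resolve_coeffs(coeffs_source)
  trajectories <- fit_trajectories(records, coeffs,
                                   drop_threshold = drop_threshold,
                                   min_run = min_run,
                                   min_seg_len = min_seg_len)
  summary <- population_summary(trajectories)
  log_msg(paste0("segmented %d puppies: %.0f%% single-curve, ",
                 "%.0f%% with >= 3 curves"),
          summary$n, 100 * summary$frac_single_curve,
          100 * summary$frac_three_plus_curves)
  list(trajectories = trajectories, summary = summary, coeffs = coeffs)
}

resolve_coeffs <- function(coeffs_source) {
  if (identical(coeffs_source, "published")) return(growth_coefficients())
  if (inherits(coeffs_source, "growth_coefficients")) return(coeffs_source)
  if (is.character(coeffs_source) && file.exists(coeffs_source)) {
    rep <- jsonlite::read_json(coeffs_source, simplifyVector = TRUE)
    if (is.null(rep$coeffs$b1)) {
      stop("fit report lacks coeffs.b1: ", coeffs_source, call. = FALSE)
    }
    return(growth_coefficients(rep$coeffs$b1, rep$coeffs$b2))
  }
  stop("`coeffs_source` must be \"published\", a growth_coefficients ",
       "object, or the path of a fit report", call. = FALSE)
}

#' Generate and export a growth chart
#'
#' @param p0_values Day-0 weights of the curves to chart, grams.
#' @param out_path Output path (`.csv`, or `.png` with
#'   `format = "png"`).
#' @param day_start,day_end Integer day range.
#' @param format `"csv"` (default) or `"png"`.
#' @param coeffs A [growth_coefficients()].
#' @return The chart data.frame, invisibly.
#' @export
run_chart <- function(p0_values, out_path, day_start = 0, day_end = 21,
                      format = c("csv", "png"),
                      coeffs = growth_coefficients()) {
  format <- match.arg(format)
  chart <- growth_chart_table(p0_values, day_start, day_end, coeffs)
  if (format == "csv") {
    write_growth_chart(chart, out_path)
  } else {
    grDevices::png(out_path, width = 900, height = 600)
    on.exit(grDevices::dev.off())
    plot_growth_chart(chart)
  }
  log_msg("wrote growth chart (%d curves, days %d-%d) to %s",
          length(p0_values), day_start, day_end, out_path)
  invisible(chart)
}

#' Validate trajectories against observed weights
#'
#' Loads a dataset, fits per-puppy trajectories and reports the
#' per-breed and pooled goodness-of-fit table (MARE, RMSE,
#' through-origin regression).
#'
#' @inheritParams run_fit_trajectories
#' @param report_path Optional JSON report path.
#' @return The metrics data.frame of [per_breed_metrics()].
#' @export
run_validate <- function(data_path, coeffs_source = "published",
                         drop_threshold = 0.03, report_path = NULL) {
  records <- load_dataset(data_path)
  coeffs <- resolve_coeffs(coeffs_source)
  trajectories <- fit_trajectories(records, coeffs,
                                   drop_threshold = drop_threshold)
  metrics <- per_breed_metrics(records, trajectories)
  pooled <- metrics[metrics$breed == "all", ]
  log_msg("pooled MARE = %.2f%%, RMSE = %.2f g, origin slope = %.4f",
          100 * pooled$mare, pooled$rmse, pooled$origin_slope)
  if (!is.null(report_path)) {
    jsonlite::write_json(metrics, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  metrics
}

#' Derived growth quantities at display precision
#'
#' Convenience wrapper over the closed-form quantities of the growth
#' law, rounded the way they are quoted in practice: percentages to one
#' decimal, days to one decimal.
#'
#' @param quantity One of `"doubling-time"`, `"daily-gain"`,
#'   `"relative-gain"`, `"mean-rate"`, `"setback-p0"`.
#' @param p0_g Day-0 weight (for `"daily-gain"`), grams.
#' @param day Day argument (meaning depends on `quantity`).
#' @param day_end Interval end for `"mean-rate"` (start is `day`).
#' @param retained_fraction For `"setback-p0"`.
#' @param multiple,start_ratio For `"doubling-time"` (target multiple
#'   of birth weight; current curve P0 over birth weight).
#' @param coeffs A [growth_coefficients()].
#' @return A named list with the raw `value` and a `display` string.
#' @export
run_derive <- function(quantity = c("doubling-time", "daily-gain",
                                    "relative-gain", "mean-rate",
                                    "setback-p0"),
                       p0_g = NULL, day = 0, day_end = 21,
                       retained_fraction = 1, multiple = 2, start_ratio = 1,
                       coeffs = growth_coefficients()) {
  quantity <- match.arg(quantity)
  out <- switch(quantity,
    "doubling-time" = {
      v <- time_to_multiple(multiple, coeffs, start_ratio)
      list(value = v, display = sprintf("%.1f days", round(v, 1)))
    },
    "daily-gain" = {
      if (is.null(p0_g)) stop("`p0_g` is required for daily-gain",
                              call. = FALSE)
      v <- daily_gain(p0_g, day, coeffs)
      list(value = v, display = sprintf("%.1f g/day", v))
    },
    "relative-gain" = {
      v <- relative_daily_gain(day, coeffs)
      list(value = v, display = sprintf("%.1f%%/day", round(100 * v, 1)))
    },
    "mean-rate" = {
      v <- mean_relative_daily_gain(day, day_end, coeffs)
      list(value = v, display = sprintf("%.1f%%/day", round(100 * v, 1)))
    },
    "setback-p0" = {
      v <- setback_adjusted_p0(retained_fraction, day, coeffs)
      list(value = v, display = sprintf("%.4f x birth weight", v))
    })
  log_msg("%s: %s", quantity, out$display)
  out
}
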