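# Goodness-of-fit statistics for validating model predictions against
# observed weights: MARE, RMSE and regression through the origin.

check_obs_pred <- function(observed, predicted) {
  if (!is.numeric(observed) || !is.numeric(predicted)) {
    stop("`observed` and `predicted` must be numeric", call. = FALSE)
  }
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(observed) < 1L) stop("need at least one observation",
                                  call. = FALSE)
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("observations and predictions must be finite", call. = FALSE)
  }
  invisible(NULL)
}

#' Mean absolute relative error
#'
#' Mean (and SD) over observations of \eqn{|O_i - P_i| / P_i}. Note the
#' denominator: the convention here divides by the *predicted* value
#' (`denominator = "predicted"`, the default, matching how this
#' validation statistic is defined for growth-curve monitoring); the
#' more common observed-denominator reading is available via
#' `denominator = "observed"`. MARE is scale-invariant.
#'
#' @param observed,predicted Weight vectors in grams, equal length;
#'   the denominator series must be positive.
#' @param denominator `"predicted"` (default) or `"observed"`.
#' @return A list: `mare`, `mare_sd`, `n_obs`, `denominator`.
#' @export
mare <- function(observed, predicted, denominator = c("predicted",
                                                      "observed")) {
  denominator <- match.arg(denominator)
  check_obs_pred(observed, predicted)
  den <- if (denominator == "predicted") predicted else observed
  if (any(den <= 0)) {
    stop(sprintf("%s values must be positive for MARE", denominator),
         call. = FALSE)
  }
  are <- abs(observed - predicted) / den
  list(mare = mean(are),
       mare_sd = if (length(are) > 1L) stats::sd(are) else 0,
       n_obs = length(are),
       denominator = denominator)
}

#' Root mean squared error
#'
#' \eqn{\sqrt{\sum (O_i - P_i)^2 / n}}, in grams; scale-equivariant.
#'
#' @inheritParams mare
#' @return RMSE in grams.
#' @export
rmse <- function(observed, predicted) {
  check_obs_pred(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

#' Regression through the origin of predicted on observed
#'
#' Fits \eqn{y = a x} with `y = predicted`, `x = observed`:
#' \eqn{a = \sum x_i y_i / \sum x_i^2}, with the uncentered
#' determination coefficient \eqn{r^2 = 1 - \sum (y - a x)^2 / \sum
#' y^2} (the centered convention is ill-defined without an intercept).
#' A well-calibrated model gives slope and r-squared near 1.
#'
#' @inheritParams mare
#' @return A list: `slope`, `r2`, `n_obs`.
#' @export
origin_regression <- function(observed, predicted) {
  check_obs_pred(observed, predicted)
  if (length(observed) < 2L) {
    stop("need at least two observations for a regression", call. = FALSE)
  }
  sxx <- sum(observed^2)
  if (sxx == 0) stop("all observed values are zero", call. = FALSE)
  slope <- sum(observed * predicted) / sxx
  syy <- sum(predicted^2)
  if (syy == 0) stop("all predicted values are zero", call. = FALSE)
  r2 <- 1 - sum((predicted - slope * observed)^2) / syy
  list(slope = slope, r2 = r2, n_obs = length(observed))
}

#' Per-breed and pooled goodness-of-fit table
#'
#' Validates fitted trajectories against the observed weights: for each
#' record assigned to a segment, the prediction is that segment's curve
#' evaluated at the record's day; off-curve (transition) days carry no
#' prediction and are excluded, with the excluded count reported. One
#' row per breed plus a pooled `all` row.
#'
#' @param records Weight records (supplies the breed of each puppy).
#' @param trajectories Trajectories from [fit_trajectories()] covering
#'   the puppies in `records`.
#' @param denominator Passed to [mare()].
#' @return A data.frame with columns `breed, n_obs, n_excluded, mare,
#'   mare_sd, rmse, origin_slope, origin_r2`; attribute
#'   `"mare_denominator"` records the MARE convention used.
#' @export
per_breed_metrics <- function(records, trajectories,
                              denominator = "predicted") {
  records <- validate_records(records)
  rows <- list()
  for (pid in unique(records$puppy_id)) {
    traj <- trajectories[[pid]]
    if (is.null(traj)) next
    a <- traj$assignments
    breed <- records$breed[records$puppy_id == pid][1L]
    rows[[pid]] <- data.frame(breed = breed, observed = a$weight_g,
                              predicted = a$predicted_g,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no puppy in `records` has a trajectory",
                          call. = FALSE)
  skipped_breeds <- setdiff(unique(records$breed),
                            unique(do.call(rbind, rows)$breed))
  if (length(skipped_breeds)) {
    message("breeds with no trajectories skipped: ",
            paste(skipped_breeds, collapse = ", "))
  }
  all_obs <- do.call(rbind, rows)

  metric_row <- function(breed, obs, pred) {
    keep <- !is.na(pred)
    m <- mare(obs[keep], pred[keep], denominator)
    o <- origin_regression(obs[keep], pred[keep])
    data.frame(breed = breed, n_obs = sum(keep), n_excluded = sum(!keep),
               mare = m$mare, mare_sd = m$mare_sd,
               rmse = rmse(obs[keep], pred[keep]),
               origin_slope = o$slope, origin_r2 = o$r2,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(all_obs, all_obs$breed), function(df) {
    metric_row(df$breed[1L], df$observed, df$predicted)
  }))
  out <- rbind(out, metric_row("all", all_obs$observed, all_obs$predicted))
  rownames(out) <- NULL
  attr(out, "mare_denominator") <- denominator
  out
}
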