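# Shared-slope indicator-variable regression on ln-weight:
#   ln y = sum_i a_i I_i + sum_j b_j x^j
# One indicator column per puppy (its intercept a_i = ln P0_i), slope
# columns x, x^2, ..., x^order common to all puppies, no global constant
# (the indicator block spans it).

#' Design matrix for the shared-slope log regression
#'
#' Builds the no-constant design on the natural-log weight scale: one
#' 0/1 indicator column per puppy followed by the polynomial age columns
#' `day, day^2, ..., day^order`. Each row's indicator block sums to 1.
#'
#' @param records Weight records (see [validate_records()]).
#' @param order Polynomial order in age, 1 to 4.
#' @return A list with `X` (design matrix, named columns), `y`
#'   (ln weight), `puppy_ids` (column order of the indicator block) and
#'   `order`.
#' @export
build_design_matrix <- function(records, order) {
  records <- validate_records(records)
  if (!is.numeric(order) || length(order) != 1L || order < 1L || order > 4L ||
      order != round(order)) {
    stop("`order` must be an integer between 1 and 4", call. = FALSE)
  }
  order <- as.integer(order)
  puppy_ids <- unique(records$puppy_id)
  counts <- table(records$puppy_id)
  starved <- names(counts)[counts < order + 1L]
  if (length(starved)) {
    stop(sprintf(
      "puppy '%s' has %d records; at least %d are needed for order %d",
      starved[1L], counts[[starved[1L]]], order + 1L, order),
      call. = FALSE)
  }
  ind <- outer(records$puppy_id, puppy_ids, `==`) * 1.0
  colnames(ind) <- paste0("I_", puppy_ids)
  slope <- outer(records$day, seq_len(order), `^`)
  colnames(slope) <- paste0("day", ifelse(seq_len(order) == 1L, "",
                                          seq_len(order)))
  list(X = cbind(ind, slope), y = log(records$weight_g),
       puppy_ids = puppy_ids, order = order)
}

#' Fit the shared-slope log-quadratic growth regression
#'
#' Ordinary least squares of ln-weight on the design of
#' [build_design_matrix()]: per-puppy intercepts (`a_i = ln P0_i`) plus
#' polynomial age coefficients shared by all puppies. Standard errors
#' come from the usual OLS covariance; R-squared is computed about the
#' response mean (the indicator block spans a constant, so the centered
#' convention is well defined) and the adjusted version charges
#' `n_puppies + order` parameters.
#'
#' By default records beyond day 28 are excluded: the growth law is a
#' neonatal-window model and its quadratic exponent must not be
#' extrapolated.
#'
#' @param records Weight records.
#' @param order Polynomial order in age (default 2, the log-quadratic
#'   law).
#' @param day_window Two-element inclusive age window used for fitting.
#' @return An object of class `global_fit`: list with `order`,
#'   `coefficients` (data.frame for the slope block: estimate, se,
#'   ci_lo, ci_hi, t, p), `intercepts` (data.frame per puppy: a_i, se,
#'   p0_g), `r2`, `adj_r2`, `resid_se`, `residuals` (puppy_id, day,
#'   residual), `n_obs`, `coeffs` (a [growth_coefficients()] when order
#'   >= 2 and estimates admit it, else NULL).
#' @export
fit_shared_slope_model <- function(records, order = 2,
                                   day_window = c(0, 28)) {
  records <- window_records(validate_records(records), day_window)
  d <- build_design_matrix(records, order)
  X <- d$X
  y <- d$y
  n <- nrow(X)
  p <- ncol(X)
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    stop("singular fit: design matrix is rank deficient (collinear ",
         "measurement pattern)", call. = FALSE)
  }
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  df_resid <- n - p
  if (df_resid <= 0) {
    stop("not enough observations for the requested order", call. = FALSE)
  }
  rss <- sum(resid^2)
  sigma2 <- rss / df_resid
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(diag(xtx_inv) * sigma2, 0))
  names(se) <- colnames(X)

  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_resid

  n_pup <- length(d$puppy_ids)
  slope_idx <- (n_pup + 1L):p
  tcrit <- stats::qt(0.975, df_resid)
  est <- beta[slope_idx]
  se_s <- se[slope_idx]
  tval <- ifelse(se_s > 0, est / se_s, NA_real_)
  coef_tab <- data.frame(
    term = colnames(X)[slope_idx],
    estimate = unname(est),
    se = unname(se_s),
    ci_lo = unname(est - tcrit * se_s),
    ci_hi = unname(est + tcrit * se_s),
    t = unname(tval),
    p = unname(2 * stats::pt(-abs(tval), df_resid)),
    stringsAsFactors = FALSE)

  intercepts <- data.frame(
    puppy_id = d$puppy_ids,
    a = unname(beta[seq_len(n_pup)]),
    se = unname(se[seq_len(n_pup)]),
    p0_g = exp(unname(beta[seq_len(n_pup)])),
    stringsAsFactors = FALSE)

  coeffs <- NULL
  if (d$order >= 2L && est[1L] > 0 && -est[2L] >= 0) {
    coeffs <- growth_coefficients(b1 = est[1L], b2 = -est[2L])
  } else if (d$order == 1L && est[1L] > 0) {
    coeffs <- growth_coefficients(b1 = est[1L], b2 = 0)
  }

  structure(list(
    order = d$order,
    coefficients = coef_tab,
    intercepts = intercepts,
    r2 = r2, adj_r2 = adj_r2,
    resid_se = sqrt(sigma2),
    residuals = data.frame(puppy_id = records$puppy_id, day = records$day,
                           residual = resid, stringsAsFactors = FALSE),
    n_obs = n,
    day_window = day_window,
    coeffs = coeffs), class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Shared-slope log regression (order %d, %d puppies, %d obs)\n",
              x$order, nrow(x$intercepts), x$n_obs))
  print(format(x$coefficients, digits = 6), row.names = FALSE)
  cat(sprintf("R2 = %.4f  adjusted R2 = %.4f  residual SE = %.4g\n",
              x$r2, x$adj_r2, x$resid_se))
  invisible(x)
}

# A slope coefficient passes the significance gate when its 95% CI
# excludes zero. Degenerate zero-SE, zero-estimate coefficients (exact
# lower-order data refit at a higher order) count as not significant.
all_slopes_significant <- function(fit) {
  ct <- fit$coefficients
  ok <- (ct$ci_lo > 0 & ct$ci_hi > 0) | (ct$ci_lo < 0 & ct$ci_hi < 0)
  ok[!is.finite(ct$t)] <- FALSE
  all(ok)
}

#' Select the polynomial order of the growth regression
#'
#' Fits orders 1..`max_order` and retains, among the orders in which
#' every shared slope coefficient differs significantly from zero (95%
#' t-based CI excludes 0), the one with the highest adjusted R-squared.
#' The per-order comparison (R2, adjusted R2, significance gate) is kept
#' in the returned fit as `order_comparison`.
#'
#' @param records Weight records.
#' @param max_order Largest order tried (default 4).
#' @param day_window Inclusive age window for fitting.
#' @return The selected `global_fit`, with an `order_comparison`
#'   data.frame attached.
#' @export
select_order <- function(records, max_order = 4, day_window = c(0, 28)) {
  if (max_order < 1) stop("`max_order` must be >= 1", call. = FALSE)
  fits <- list()
  comparison <- data.frame(order = integer(), r2 = numeric(),
                           adj_r2 = numeric(), all_significant = logical())
  for (ord in seq_len(max_order)) {
    fit <- tryCatch(fit_shared_slope_model(records, ord, day_window),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      comparison <- rbind(comparison, data.frame(
        order = ord, r2 = NA_real_, adj_r2 = NA_real_,
        all_significant = FALSE))
      next
    }
    fits[[ord]] <- fit
    comparison <- rbind(comparison, data.frame(
      order = ord, r2 = fit$r2, adj_r2 = fit$adj_r2,
      all_significant = all_slopes_significant(fit)))
  }
  eligible <- comparison$order[comparison$all_significant %in% TRUE]
  if (!length(eligible)) {
    err <- simpleError(
      "order selection failed: no order has all slope coefficients significant")
    err$comparison <- comparison
    stop(err)
  }
  best <- eligible[which.max(comparison$adj_r2[match(eligible,
                                                     comparison$order)])]
  fit <- fits[[best]]
  fit$order_comparison <- comparison
  fit
}

#' Residual diagnostics for a global fit
#'
#' Two checks of the fitted growth regression, both on the ln-weight
#' residuals: (i) per-sex residual mean with a two-sided one-sample
#' t test against zero (the model should be unbiased for both sexes);
#' (ii) per-puppy lag-1 residual autocorrelation, flagged when |r|
#' exceeds the approximate 95% bound 1.96/sqrt(m) for that puppy's
#' series length m. Puppies with fewer than 4 residuals are skipped
#' (listed in `skipped`).
#'
#' @param fit A `global_fit`.
#' @param records The records the fit was produced from (supplies sex).
#' @return A list with `by_sex` (sex, n, mean_residual, t, p),
#'   `autocorrelation` (puppy_id, n, lag1, bound, flagged) and
#'   `skipped`.
#' @export
residual_diagnostics <- function(fit, records) {
  stopifnot(inherits(fit, "global_fit"))
  records <- validate_records(records)
  res <- fit$residuals
  sex_of <- records$sex[match(paste(res$puppy_id, res$day),
                              paste(records$puppy_id, records$day))]

  by_sex <- do.call(rbind, lapply(split(res$residual, sex_of), function(r) {
    if (length(r) < 2L || stats::sd(r) == 0) {
      data.frame(n = length(r), mean_residual = mean(r),
                 t = NA_real_, p = NA_real_)
    } else {
      tt <- stats::t.test(r, mu = 0)
      data.frame(n = length(r), mean_residual = mean(r),
                 t = unname(tt$statistic), p = tt$p.value)
    }
  }))
  by_sex <- cbind(sex = rownames(by_sex), by_sex)
  rownames(by_sex) <- NULL

  ac_rows <- list()
  skipped <- character()
  for (pid in unique(res$puppy_id)) {
    r <- res$residual[res$puppy_id == pid][order(res$day[res$puppy_id == pid])]
    m <- length(r)
    if (m < 4L) {
      skipped <- c(skipped, pid)
      next
    }
    rc <- r - mean(r)
    denom <- sum(rc^2)
    # residuals at numerical zero (an exact fit) carry no signal
    lag1 <- if (denom > m * 1e-16) sum(rc[-1L] * rc[-m]) / denom else 0
    bound <- 1.96 / sqrt(m)
    ac_rows[[pid]] <- data.frame(puppy_id = pid, n = m, lag1 = lag1,
                                 bound = bound, flagged = abs(lag1) > bound,
                                 stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    message("skipped (fewer than 4 residuals): ",
            paste(skipped, collapse = ", "))
  }
  list(by_sex = by_sex,
       autocorrelation = if (length(ac_rows)) {
         ac <- do.call(rbind, ac_rows); rownames(ac) <- NULL; ac
       } else {
         data.frame(puppy_id = character(), n = integer(), lag1 = numeric(),
                    bound = numeric(), flagged = logical())
       },
       skipped = skipped)
}

# Mean observed relative daily gain of one puppy over consecutive-day
# pairs: average of (w_{d+1} - w_d) / w_d.
observed_relative_gain <- function(day, weight_g) {
  o <- order(day)
  day <- day[o]; weight_g <- weight_g[o]
  consec <- which(diff(day) == 1)
  if (!length(consec)) return(NA_real_)
  mean((weight_g[consec + 1L] - weight_g[consec]) / weight_g[consec])
}

#' Compare observed growth rates between sexes
#'
#' For each puppy, the mean observed relative daily gain over
#' consecutive-day pairs; then a two-sample pooled-variance Student
#' t test between male and female puppies (Welch's unequal-variance
#' test available via `pooled = FALSE`). The growth law predicts no sex
#' effect in the neonatal window.
#'
#' @param records Weight records with at least two puppies of each sex.
#' @param pooled Use the pooled-variance t test (default); `FALSE` for
#'   Welch.
#' @return A list: `by_sex` (sex, n_puppies, mean, sd), `t`, `df`, `p`,
#'   and `per_puppy` rates.
#' @export
compare_sex_growth_rates <- function(records, pooled = TRUE) {
  records <- validate_records(records)
  records <- records[records$sex %in% c("male", "female"), , drop = FALSE]
  per_puppy <- do.call(rbind, lapply(split(records, records$puppy_id),
    function(df) data.frame(puppy_id = df$puppy_id[1L], sex = df$sex[1L],
                            rate = observed_relative_gain(df$day, df$weight_g),
                            stringsAsFactors = FALSE)))
  per_puppy <- per_puppy[is.finite(per_puppy$rate), , drop = FALSE]
  n_by_sex <- table(factor(per_puppy$sex, levels = c("male", "female")))
  if (any(n_by_sex < 2L)) {
    stop("need at least 2 puppies per sex with consecutive-day measurements",
         call. = FALSE)
  }
  males <- per_puppy$rate[per_puppy$sex == "male"]
  females <- per_puppy$rate[per_puppy$sex == "female"]
  if (stats::sd(males) < 1e-12 && stats::sd(females) < 1e-12 &&
      abs(mean(males) - mean(females)) < 1e-12) {
    # two constant, identical groups: no evidence of any difference
    tt <- list(statistic = c(t = 0),
               parameter = c(df = length(males) + length(females) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(males, females, var.equal = pooled)
  }
  list(
    by_sex = data.frame(
      sex = c("male", "female"),
      n_puppies = c(length(males), length(females)),
      mean = c(mean(males), mean(females)),
      sd = c(stats::sd(males), stats::sd(females))),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    method = if (pooled) "pooled-variance t" else "Welch t",
    per_puppy = per_puppy)
}
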