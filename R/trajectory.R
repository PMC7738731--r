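# Per-puppy piecewise description of a weight series with the global
# curve shape held fixed: an ordered sequence of growth curves with
# strictly decreasing P0 ("falls"), plus off-curve transition days.
#
# Because the shape g(x) = exp(b1*x - b2*x^2) is shared, every record
# carries an implied log curve offset c_i = ln(w_i) - ln(g(x_i)); a
# segment is a run of records with (approximately) constant offset, and
# a fall is a confirmed downward step in that offset.

#' Least-squares curve offset for a weight series
#'
#' Closed-form linear-space least squares for the day-0 value of the
#' curve best fitting a set of measurements with the global shape held
#' fixed: with \eqn{g_i = \exp(b_1 x_i - b_2 x_i^2)}, the minimizer of
#' \eqn{\sum (w_i - P_0 g_i)^2} is \eqn{\hat P_0 = \sum w_i g_i / \sum
#' g_i^2}.
#'
#' @param series A data.frame with columns `day` and `weight_g` (a
#'   single puppy's measurements).
#' @param coeffs A [growth_coefficients()].
#' @param day_window Optional inclusive `(lo, hi)` age window; records
#'   outside it are ignored.
#' @return Estimated P0 in grams.
#' @examples
#' s <- data.frame(day = 0:10, weight_g = predict_weight(300, 0:10))
#' estimate_p0(s)   # exactly 300
#' @export
estimate_p0 <- function(series, coeffs = growth_coefficients(),
                        day_window = NULL) {
  coeffs <- as_growth_coefficients(coeffs)
  stopifnot(is.data.frame(series), all(c("day", "weight_g") %in% names(series)))
  if (!is.null(day_window)) {
    series <- window_records(series, day_window)
  }
  if (nrow(series) < 2L) {
    stop("need at least 2 records to estimate P0", call. = FALSE)
  }
  if (any(series$weight_g <= 0)) stop("weights must be positive", call. = FALSE)
  p0_lsq(series$day, series$weight_g, coeffs)
}

p0_lsq <- function(day, weight_g, coeffs) {
  g <- growth_factor(day, coeffs)
  sum(weight_g * g) / sum(g^2)
}

# Iteratively expel members that stick out of a segment's residual
# distribution (descending transition days absorbed while the running
# estimate drifted): worst offender first, while its deviation from the
# median residual exceeds max(3 * mad, 0.005) and at least min_keep
# members remain. For noisy series 3 * mad is ~3 sigma and essentially
# nothing is pruned; for clean series mad ~ 0 and any absorbed
# transition day is expelled exactly.
prune_members <- function(members, day, weight_g, c_off, coeffs,
                          min_keep = 2L) {
  repeat {
    if (length(members) <= min_keep) break
    level <- log(p0_lsq(day[members], weight_g[members], coeffs))
    resid <- c_off[members] - level
    dev <- abs(resid - stats::median(resid))
    cut <- max(3 * stats::mad(resid), 0.005)
    worst <- which.max(dev)
    if (dev[worst] <= cut) break
    members <- members[-worst]
  }
  members
}

# Globally optimal partition of the offset series into constant-level
# segments, short off-curve transitions and isolated outliers, by
# dynamic programming over a penalized least-squares criterion. The
# structural assumptions mirror the observed growth process: a fall
# passes through at most `max_trans` off-curve transition days (cheap,
# cost rho_t each); a puppy may spend up to `max_lead` days before
# joining its first curve (the initial-loss path, rho_t each); within
# a segment up to two gross outliers may be paid off at rho_o each;
# every segment beyond the first costs lambda. Minimizing total cost
# yields the most parsimonious sequence of curves consistent with the
# scatter `sigma` (floored so clean series behave as the exact
# zero-noise limit). Levels that fail to drop by more than `threshold`
# are merged afterwards.
dp_partition <- function(c_off, sigma, threshold, min_seg_len,
                         max_trans = 2L, max_lead = 4L) {
  n <- length(c_off)
  rho_t <- 1.75               # expected transition / loss-path day
  rho_o <- 2 * log(n) + 2     # gross outlier inside or after a segment
  lambda <- 1.5 * log(n)      # opening one more curve

  # A pre-curve phase (initial stagnation or loss) always descends in
  # offset terms by at least the daily growth a curve would deliver;
  # flat-offset records are on a curve and cannot be explained away as
  # leading days. lead_ok[j]: records 1..j form a valid descent.
  lead_ok <- c(TRUE, rep(FALSE, max(n - 1L, 0L)))
  if (n >= 2L) {
    for (j in 2:min(max_lead, n)) {
      if (!lead_ok[j - 1L] || c_off[j] - c_off[j - 1L] > -threshold) break
      lead_ok[j] <- TRUE
    }
  }

  # interval cost: best over trimming t = 0, 1, 2 worst interior members
  int_cost <- matrix(Inf, n, n)
  int_members <- vector("list", n * n)
  for (a in seq_len(n)) {
    for (b in a:n) {
      idx <- a:b
      if (length(idx) < min_seg_len) next
      best <- Inf
      best_members <- idx
      cur <- idx
      for (t in 0:2) {
        if (length(cur) < min_seg_len) break
        r <- c_off[cur] - mean(c_off[cur])
        cost <- sum(r^2) / sigma^2 + t * rho_o
        if (cost < best) {
          best <- cost
          best_members <- cur
        }
        interior <- setdiff(cur, c(a, b))
        if (!length(interior)) break
        r_int <- abs(c_off[interior] - mean(c_off[cur]))
        cur <- setdiff(cur, interior[which.max(r_int)])
      }
      int_cost[a, b] <- best
      int_members[[(a - 1L) * n + b]] <- best_members
    }
  }

  # f[b + 1]: best cost of records 1..b with a segment ending exactly
  # at b (f[1] is the empty prefix); backpointers record the segment
  # start and the index the previous segment ended at (0 = none)
  f <- rep(Inf, n + 1L)
  f_from <- integer(n + 1L)
  f_prev <- integer(n + 1L)
  for (b in seq_len(n)) {
    for (a in seq_len(b)) {
      if (!is.finite(int_cost[a, b])) next
      # opener 1: this is the first segment, a - 1 leading off records
      if (a - 1L <= max_lead && (a == 1L || lead_ok[a - 1L])) {
        cost <- lambda + (a - 1L) * rho_t + int_cost[a, b]
        if (cost < f[b + 1L]) {
          f[b + 1L] <- cost
          f_from[b + 1L] <- a
          f_prev[b + 1L] <- 0L
        }
      }
      # opener 2: a fall from a previous segment, g transition days
      for (g in seq_len(max_trans)) {
        e <- a - 1L - g
        if (e < 1L || !is.finite(f[e + 1L])) next
        cost <- f[e + 1L] + g * rho_t + lambda + int_cost[a, b]
        if (cost < f[b + 1L]) {
          f[b + 1L] <- cost
          f_from[b + 1L] <- a
          f_prev[b + 1L] <- e
        }
      }
    }
  }
  # trailing records after the last segment are gross outliers
  total <- f[seq_len(n) + 1L] + (n - seq_len(n)) * rho_o
  b_end <- which.min(total)
  if (!is.finite(total[b_end])) return(rep(NA_integer_, n))

  seg_of <- rep(NA_integer_, n)
  segments <- list()
  b <- b_end
  repeat {
    a <- f_from[b + 1L]
    segments[[length(segments) + 1L]] <- int_members[[(a - 1L) * n + b]]
    if (f_prev[b + 1L] == 0L) break
    b <- f_prev[b + 1L]
  }
  segments <- rev(segments)
  # merge adjacent levels whose drop does not exceed the membership
  # threshold, or is within three standard errors of zero given the
  # scatter (capped at twice the threshold so large steps always
  # stand); for clean series sigma is at its floor and only the
  # absolute criterion bites
  k <- 2L
  while (k <= length(segments)) {
    lvl_prev <- mean(c_off[segments[[k - 1L]]])
    lvl <- mean(c_off[segments[[k]]])
    se <- sigma * sqrt(1 / length(segments[[k - 1L]]) +
                         1 / length(segments[[k]]))
    if (lvl_prev - lvl <= max(threshold,
                              min(3.5 * se, 2 * threshold))) {
      segments[[k - 1L]] <- sort(c(segments[[k - 1L]], segments[[k]]))
      segments[[k]] <- NULL
      if (k > 2L) k <- k - 1L
    } else {
      k <- k + 1L
    }
  }
  for (s in seq_along(segments)) seg_of[segments[[s]]] <- s
  seg_of
}


# Grow a maximal run of curve-consistent points forward from `start`.
# `c_off` is the per-point implied log offset; membership is judged by
# the log residual against the running least-squares P0. A single
# out-of-threshold point is skipped as a hole; two consecutive
# violations stop the run, recording the side of the first violator.
grow_run <- function(start, day, weight_g, c_off, coeffs, threshold) {
  n <- length(day)
  members <- start
  holes <- integer()
  level <- c_off[start]
  k <- start + 1L
  reason <- "end"
  while (k <= n) {
    resid <- c_off[k] - level
    # a run's first pair is judged jointly (each member within the
    # threshold of their common fit), i.e. at twice the single-point
    # tolerance; later members are judged against the running estimate
    tol <- if (length(members) == 1L) 2 * threshold else threshold
    if (abs(resid) <= tol) {
      members <- prune_members(c(members, k), day, weight_g, c_off, coeffs)
      level <- log(p0_lsq(day[members], weight_g[members], coeffs))
      k <- k + 1L
    } else if (k + 1L <= n && abs(c_off[k + 1L] - level) <= threshold) {
      holes <- c(holes, k)      # isolated excursion inside the run
      k <- k + 1L
    } else if (k == n) {
      reason <- "trail"         # single violating record at series end
      break
    } else {
      # two consecutive violations stop the run; only a concordant
      # step back UP is the phantom-fall signature, a mixed pair is
      # ordinary scatter at the run boundary
      r2 <- c_off[k + 1L] - level
      reason <- if (resid > 0 && r2 > 0) "up"
                else if (resid < 0 && r2 < 0) "down"
                else "mixed"
      break
    }
  }
  list(members = members, holes = holes, level = level,
       next_idx = k, reason = reason)
}

# Pick a segment-opening run among candidate start indices.
# `require_drop_signature` enforces, in addition to the minimum length
# and the strictly-lower-offset constraint, that the run ends either at
# the series end or in a further downward step: a run that stops
# because the following points sit ABOVE it is the signature of a noise
# excursion mistaken for a fall, and is rejected. For a post-fall
# opening the longest admissible run wins (transition-day starts grow
# short runs, the true curve start grows a long one), earliest on
# ties; for the initial opening the earliest admissible run wins (the
# first curve starts as soon as the measurements lock onto a curve).
pick_opening_run <- function(starts, day, weight_g, c_off, coeffs, threshold,
                             min_seg_len, prev_level = Inf,
                             require_drop_signature = FALSE,
                             prefer = c("longest", "earliest")) {
  prefer <- match.arg(prefer)
  best <- NULL
  for (j in starts) {
    run <- grow_run(j, day, weight_g, c_off, coeffs, threshold)
    if (length(run$members) < min_seg_len) next
    if (run$level >= prev_level) next
    # a short run ending in a concordant step back up is a noise pair
    # mistaken for a fall; a long one is a real segment that happens to
    # end at an upward excursion
    if (require_drop_signature && run$reason == "up" &&
        length(run$members) <= 3L) next
    # a run whose offsets descend strictly through more than the
    # threshold is a staircase of transition days, not a curve
    if (require_drop_signature && length(run$members) >= 3L) {
      cm <- c_off[run$members]
      if (all(diff(cm) < 0) && max(cm) - min(cm) > threshold) next
    }
    run$start <- j
    run$spread <- sqrt(mean((c_off[run$members] - run$level)^2))
    # the initial opening anchors at the first viable start: the first
    # curve begins as soon as the measurements lock onto a curve
    if (prefer == "earliest") return(run)
    # longest admissible run wins; among equal lengths the internally
    # tightest one (a run anchored on descending transition days has a
    # systematically larger spread than one on the actual curve)
    if (is.null(best) || length(run$members) > length(best$members) ||
        (length(run$members) == length(best$members) &&
         run$spread < best$spread)) {
      best <- run
    }
  }
  best
}

#' Segment a weight series into successive growth curves
#'
#' Mechanizes the identification of the growth curves a puppy follows,
#' in two stages. First, a greedy forward pass over the day-sorted
#' series: the current segment's P0 is re-estimated by [estimate_p0()]
#' as records accrue, and a switch to a lower curve ("fall") is
#' confirmed when the log residual \eqn{\ln w - \ln(\hat P_0 g(x))}
#' stays below `-drop_threshold` for `min_run` consecutive records, at
#' which point the next segment is opened from the longest consistent
#' run of at least `min_seg_len` records with strictly lower P0;
#' records above `+drop_threshold` never open a higher curve. Second, a
#' global refinement: a penalized least-squares partition (dynamic
#' programming over the implied log curve offsets, with the series'
#' own scatter as scale) settles the exact boundaries, the off-curve
#' transition days and the number of curves, arbitrating the marginal
#' split/merge decisions a forward threshold pass cannot resolve.
#' Adjacent curves whose P0s are not separated by more than the scatter
#' supports are treated as one curve, so the reported P0 sequence is
#' always strictly decreasing.
#'
#' @param series One puppy's records: data.frame with `day` and
#'   `weight_g` (extra columns such as `puppy_id` are carried through).
#' @param coeffs Global [growth_coefficients()].
#' @param drop_threshold Log-residual threshold (~ fractional weight
#'   deviation) separating on-curve scatter from another curve; default
#'   0.03, above the ~2% measurement noise floor.
#' @param min_run Consecutive below-threshold records needed to confirm
#'   a fall (default 2).
#' @param min_seg_len Minimum records per segment (default 2).
#' @return An object of class `trajectory_fit`: `puppy_id`, `segments`
#'   (data.frame `segment, start_day, end_day, p0_g, n_points`),
#'   `assignments` (per record: `day, weight_g, segment, predicted_g`;
#'   `segment` is NA off-curve), `off_curve_days`, `n_curves`,
#'   `pattern` (`single_curve`/`multi_curve`), `gained_from_day0`
#'   (logical, NA when day 0 was not measured), `days_to_first_curve`,
#'   `initial_loss_fraction`.
#' @export
segment_trajectory <- function(series, coeffs = growth_coefficients(),
                               drop_threshold = 0.03, min_run = 2,
                               min_seg_len = 2) {
  coeffs <- as_growth_coefficients(coeffs)
  stopifnot(is.data.frame(series), all(c("day", "weight_g") %in% names(series)))
  series <- series[order(series$day), , drop = FALSE]
  day <- series$day
  weight_g <- series$weight_g
  n <- length(day)
  if (n < 3L) stop("need at least 3 records to segment", call. = FALSE)
  if (any(weight_g <= 0)) stop("weights must be positive", call. = FALSE)
  if (anyDuplicated(day)) stop("duplicate days in series", call. = FALSE)
  c_off <- log(weight_g) - log(growth_factor(day, coeffs))

  seg_of <- rep(NA_integer_, n)
  seg_id <- 0L
  seg_levels <- numeric()

  open_first <- pick_opening_run(seq_len(n), day, weight_g, c_off, coeffs,
                                 drop_threshold, min_seg_len,
                                 prefer = "earliest")
  if (is.null(open_first)) {
    stop("unsegmentable series: no run of at least min_seg_len ",
         "curve-consistent records", call. = FALSE)
  }
  seg_id <- 1L
  members <- open_first$members
  seg_of[members] <- seg_id
  # isolated excursions inside the run are scatter, not transitions
  seg_of[open_first$holes] <- seg_id
  members <- sort(c(members, open_first$holes))
  level <- open_first$level
  i <- open_first$next_idx

  pending <- integer()      # consecutive below-threshold records
  pending_up <- integer()   # consecutive above-threshold records

  # add records to the current segment, then expel any member the
  # segment's own residual distribution rejects (absorbed transition
  # days); keeps `members`, `seg_of` and `level` in sync
  absorb <- function(new_idx) {
    grown <- sort(c(members, new_idx))
    seg_of[new_idx] <<- seg_id
    kept <- prune_members(grown, day, weight_g, c_off, coeffs)
    seg_of[setdiff(grown, kept)] <<- NA_integer_
    members <<- kept
    level <<- log(p0_lsq(day[kept], weight_g[kept], coeffs))
  }

  while (i <= n) {
    resid <- c_off[i] - level
    if (resid < -drop_threshold) {
      if (length(pending_up) == 1L) {
        # isolated upward excursion: scatter, keep it on the curve
        absorb(pending_up)
      }
      pending_up <- integer()
      pending <- c(pending, i)
      if (length(pending) >= min_run) {
        # noise-adaptive confirmation: the run's mean shortfall must
        # exceed the threshold by its own standard error, estimated
        # from the current segment's residual scatter (zero for clean
        # series), before a pair of low records counts as a fall
        sig_m <- sqrt(mean((c_off[members] - level)^2))
        confirmed <- mean(c_off[pending] - level) <
          -(drop_threshold + sig_m / sqrt(length(pending)))
        # the next curve starts at the first below-threshold record or
        # within the at-most-two off-curve transition days after it
        cand <- if (confirmed) {
          pick_opening_run(
            pending[1L]:min(pending[1L] + 2L, n),
            day, weight_g, c_off, coeffs, drop_threshold, min_seg_len,
            prev_level = level, require_drop_signature = TRUE)
        } else NULL
        # the new curve must be separated from the current one by more
        # than the scatter supports, or it is the same curve
        if (!is.null(cand) &&
            level - cand$level <
              max(drop_threshold,
                  min(3 * sig_m * sqrt(1 / length(members) +
                                         1 / length(cand$members)),
                      2 * drop_threshold))) {
          cand <- NULL
        }
        if (!is.null(cand)) {
          # fall confirmed: records between segments stay off-curve
          seg_levels <- c(seg_levels, level)
          seg_id <- seg_id + 1L
          members <- sort(c(cand$members, cand$holes))
          seg_of[members] <- seg_id
          level <- cand$level
          i <- cand$next_idx
          pending <- integer()
          next
        } else if (confirmed) {
          # transient excursion, not a lower curve: leave it off-curve
          pending <- integer()
        }
        # not confirmed: keep accumulating evidence in `pending`
      }
    } else if (resid > drop_threshold) {
      # records above the curve never open a higher segment: a single
      # one is scatter, a sustained excursion stays off-curve so it
      # cannot drag the curve estimate upward
      if (length(pending) && length(pending) < min_run) {
        absorb(pending)
      }
      pending <- integer()
      pending_up <- c(pending_up, i)
      if (length(pending_up) >= min_run) {
        pending_up <- integer()   # confirmed upward excursion: off-curve
      }
    } else {
      scatter <- integer()
      if (length(pending) && length(pending) < min_run) {
        scatter <- pending        # unconfirmed dip: ordinary scatter
      }
      if (length(pending_up) == 1L) {
        scatter <- c(scatter, pending_up)
      }
      pending <- integer()
      pending_up <- integer()
      absorb(c(scatter, i))
    }
    i <- i + 1L
  }
  if (length(pending) && length(pending) < min_run) {
    absorb(pending)
  }
  if (length(pending_up) == 1L) {
    absorb(pending_up)
  }
  seg_levels <- c(seg_levels, level)

  # Global refinement: the greedy pass supplies the scatter estimate;
  # the penalized least-squares partition then settles the segment
  # boundaries and the off-curve set exactly, arbitrating the marginal
  # split/merge calls that a forward pass decides by threshold.
  # scatter from first differences of the offset series: within-curve
  # day-to-day differences are noise * sqrt(2). The 35th percentile of
  # |diff| (scaled by the matching half-normal quantile) is used rather
  # than the median because in a series with an initial loss phase and
  # several falls, structural differences -- which are not noise -- can
  # be the majority, while at least ~40% of differences always lie
  # within curves.
  # Two scaled estimates: the median, efficient when noise dominates,
  # and the 35th percentile, robust when structural differences (loss
  # path, transitions, falls) are the majority -- at least ~40% of
  # differences always lie within curves. A 35th percentile far below
  # the median marks the bimodal clean-series case (near-zero
  # within-curve differences next to structural ones), where the
  # median would mistake structure for noise.
  adiff <- abs(diff(c_off))
  med_est <- 1.4826 * stats::median(adiff) / sqrt(2)
  q_est <- unname(stats::quantile(adiff, 0.35)) /
    (sqrt(2) * stats::qnorm(0.675))
  sig_hat <- max(if (q_est < 0.5 * med_est) q_est else med_est, 0.003)
  seg_of <- dp_partition(c_off, sig_hat, drop_threshold, min_seg_len)
  if (all(is.na(seg_of))) {
    stop("unsegmentable series: no run of at least min_seg_len ",
         "curve-consistent records", call. = FALSE)
  }

  # Trim pass: expel members that stick out of their segment's
  # residual distribution (absorbed transition days), keeping at least
  # min_seg_len.
  for (s in sort(unique(seg_of[!is.na(seg_of)]))) {
    idx <- which(seg_of == s)
    if (length(idx) <= min_seg_len) next
    kept <- prune_members(idx, day, weight_g, c_off, coeffs,
                          min_keep = min_seg_len)
    seg_of[setdiff(idx, kept)] <- NA_integer_
  }

  # Final per-segment P0 from assigned records; adjacent segments whose
  # final P0s are not separated by more than the membership threshold
  # are the same curve and merge, guaranteeing strictly decreasing P0.
  repeat {
    ids <- sort(unique(seg_of[!is.na(seg_of)]))
    idx_of <- lapply(ids, function(s) which(seg_of == s))
    p0s <- vapply(idx_of, function(idx) {
      p0_lsq(day[idx], weight_g[idx], coeffs)
    }, numeric(1))
    flip <- which(diff(log(p0s)) >= -drop_threshold)
    if (!length(flip)) break
    seg_of[seg_of == ids[flip[1L] + 1L]] <- ids[flip[1L]]
  }
  seg_of <- match(seg_of, ids)
  n_segs <- length(ids)
  segments <- do.call(rbind, lapply(seq_len(n_segs), function(s) {
    idx <- which(seg_of == s)
    data.frame(segment = s,
               start_day = min(day[idx]), end_day = max(day[idx]),
               p0_g = p0_lsq(day[idx], weight_g[idx], coeffs),
               n_points = length(idx))
  }))
  stopifnot(all(diff(segments$p0_g) < 0))

  predicted <- ifelse(is.na(seg_of), NA_real_,
                      segments$p0_g[seg_of] * growth_factor(day, coeffs))
  assignments <- data.frame(day = day, weight_g = weight_g,
                            segment = seg_of, predicted_g = predicted)

  first_idx <- which(seg_of == 1L)
  has_day0 <- 0 %in% day
  gained_from_day0 <- if (!has_day0) {
    NA
  } else {
    # the first curve is the birth-weight curve if the day-0 record
    # lies on it, or if its P0 matches the day-0 weight within the
    # scatter threshold (a setback curve sits at least ~12% lower, so
    # the two conditions cannot both misfire)
    day0_in_first <- 0 %in% day[first_idx]
    day0_w <- weight_g[day == 0][1L]
    day0_in_first || abs(log(segments$p0_g[1L] / day0_w)) <= drop_threshold
  }
  initial_loss_fraction <- if (has_day0) {
    early <- weight_g[day <= 2] / weight_g[day == 0][1L]
    if (min(early) < 1) min(early) else NA_real_
  } else NA_real_

  structure(list(
    puppy_id = if ("puppy_id" %in% names(series)) series$puppy_id[1L] else NA,
    segments = segments,
    assignments = assignments,
    off_curve_days = day[is.na(seg_of)],
    n_curves = n_segs,
    pattern = if (n_segs == 1L) "single_curve" else "multi_curve",
    gained_from_day0 = gained_from_day0,
    days_to_first_curve = segments$start_day[1L],
    initial_loss_fraction = initial_loss_fraction,
    drop_threshold = drop_threshold,
    coeffs = coeffs), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("Trajectory of puppy %s: %d curve(s) [%s]\n",
              x$puppy_id, x$n_curves, x$pattern))
  print(format(x$segments, digits = 5), row.names = FALSE)
  if (length(x$off_curve_days)) {
    cat("off-curve days:", paste(x$off_curve_days, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Growth-pattern summary of one trajectory
#'
#' Extracts the monitoring-relevant features of a segmented series:
#' whether the puppy gained from day 0 (its day-0 record lies on the
#' first curve), the deepest early loss as a fraction of birth weight
#' (minimum of `w_d / w_0` over days 0-2, when below 1), the day its
#' first curve starts, and the number of curves followed.
#'
#' @param traj A `trajectory_fit`.
#' @return A one-row data.frame: `puppy_id, n_curves, pattern,
#'   gained_from_day0, initial_loss_fraction, days_to_first_curve`.
#' @export
classify_pattern <- function(traj) {
  stopifnot(inherits(traj, "trajectory_fit"))
  data.frame(puppy_id = traj$puppy_id,
             n_curves = traj$n_curves,
             pattern = traj$pattern,
             gained_from_day0 = traj$gained_from_day0,
             initial_loss_fraction = traj$initial_loss_fraction,
             days_to_first_curve = traj$days_to_first_curve,
             stringsAsFactors = FALSE)
}

#' Segment every puppy in a dataset
#'
#' Runs [segment_trajectory()] per puppy on a long-format record table.
#'
#' @param records Weight records (see [validate_records()]).
#' @inheritParams segment_trajectory
#' @return A named list of `trajectory_fit` objects, one per puppy.
#' @export
fit_trajectories <- function(records, coeffs = growth_coefficients(),
                             drop_threshold = 0.03, min_run = 2,
                             min_seg_len = 2) {
  records <- validate_records(records)
  out <- lapply(split(records, records$puppy_id), segment_trajectory,
                coeffs = coeffs, drop_threshold = drop_threshold,
                min_run = min_run, min_seg_len = min_seg_len)
  out[unique(records$puppy_id)]
}

#' Population-level growth-pattern proportions
#'
#' Aggregates [classify_pattern()] rows over a set of trajectories:
#' fraction following a single curve, fraction following three or more,
#' fraction gaining from day 0, fraction joining their first curve
#' within 3 days of a drop (among puppies with an initial loss), and
#' the full distribution of the number of curves.
#'
#' @param trajectories A list of `trajectory_fit` objects (e.g. from
#'   [fit_trajectories()]).
#' @return A list: `n`, `frac_single_curve`, `frac_three_plus_curves`,
#'   `frac_gained_from_day0`, `frac_joined_within_3_days`,
#'   `n_curves_distribution`, `patterns` (per-puppy table).
#' @export
population_summary <- function(trajectories) {
  if (!length(trajectories)) {
    stop("`trajectories` must contain at least one trajectory",
         call. = FALSE)
  }
  pat <- do.call(rbind, lapply(trajectories, classify_pattern))
  rownames(pat) <- NULL
  droppers <- pat[!is.na(pat$gained_from_day0) & !pat$gained_from_day0, ,
                  drop = FALSE]
  list(
    n = nrow(pat),
    frac_single_curve = mean(pat$n_curves == 1L),
    frac_three_plus_curves = mean(pat$n_curves >= 3L),
    frac_gained_from_day0 = mean(pat$gained_from_day0, na.rm = TRUE),
    frac_joined_within_3_days = if (nrow(droppers)) {
      mean(droppers$days_to_first_curve <= 3)
    } else NA_real_,
    n_curves_distribution = table(pat$n_curves),
    patterns = pat)
}
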