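# Seeded generator of litters and daily weight series with the
# population structure reported for breeder-recorded neonatal data:
# breed-specific birth-weight ranges, an initial gain/stagnation/loss
# phase, random downward curve switches ("falls") with short off-curve
# transitions, multiplicative measurement noise and the 5-g resolution
# of a kitchen-type scale. Every simulated puppy carries its ground
# truth (curve P0s, fall days, off-curve days) so recovery can be
# tested without re-inferring the generative parameters.

#' Reference breed table for the simulator
#'
#' Birth-weight ranges (grams), litter counts and litter-size ranges
#' for the nineteen toy-to-giant breeds of the validation population,
#' from Chihuahua (130-145 g) to Neapolitan Mastiff (600-1,000 g).
#'
#' @return A data.frame: `name, birth_weight_lo_g, birth_weight_hi_g,
#'   litters, litter_size_lo, litter_size_hi`.
#' @export
default_breed_table <- function() {
  tab <- rbind(
    c("Chihuahua",                     130,  145,  4,  2,  4),
    c("Yorkshire Terrier",              70,  165,  2,  4,  5),
    c("Portuguese Podengo",            115,  200,  2,  4,  5),
    c("Lhasa Apso",                    130,  150,  1,  2,  2),
    c("Parson Russell Terrier",        100,  250,  2,  4,  6),
    c("Cavalier King Charles Spaniel", 130,  230,  5,  2,  7),
    c("Shetland Sheepdog",             200,  280,  1,  4,  4),
    c("Standard Dachshund",            240,  340,  1,  6,  6),
    c("Whippet",                       240,  400,  5,  6,  9),
    c("Bulldog",                       240,  400,  3,  4,  6),
    c("Bull Terrier",                  300,  450,  2,  1,  7),
    c("Shar Pei",                      360,  440,  4,  3,  7),
    c("Belgian Shepherd-Laekenois",    240,  410,  3,  6,  8),
    c("Basset Hound",                  350,  450,  2,  5,  6),
    c("Golden Retriever",              360,  540,  4,  5, 10),
    c("Rhodesian Ridgeback",           360,  550,  1, 10, 10),
    c("Old English Sheepdog",          265,  500, 12,  2, 10),
    c("Great Dane",                    500,  930,  4,  3,  6),
    c("Neapolitan Mastiff",            600, 1000,  2,  9,  9))
  data.frame(name = tab[, 1L],
             birth_weight_lo_g = as.numeric(tab[, 2L]),
             birth_weight_hi_g = as.numeric(tab[, 3L]),
             litters = as.integer(tab[, 4L]),
             litter_size_lo = as.integer(tab[, 5L]),
             litter_size_hi = as.integer(tab[, 6L]),
             stringsAsFactors = FALSE)
}

#' Simulator configuration
#'
#' Parameters of the synthetic weight-series generator. The defaults
#' are the documented calibration: 48% of puppies gain from day 0, a
#' third lose up to 20% of birth weight in the first 24-48 h (the rest
#' stagnate briefly), all join a curve within `max_days_to_join_curve`
#' days, 10% follow a single curve and two-thirds three or more, fall
#' magnitudes are uniform on 5-15% of the current P0 with at least
#' `fall_min_gap_days` between falls, multiplicative noise has ln-scale
#' SD 0.026 (so the expected absolute relative error
#' \eqn{\sigma\sqrt{2/\pi}} is near the 2.07% validation MARE), and
#' weights are read off a 5-g-division scale.
#'
#' @param breeds Breed table as in [default_breed_table()].
#' @param p_gain_from_day0 Probability of gaining from day 0.
#' @param p_initial_loss Probability of an initial loss phase.
#' @param initial_loss_max Largest initial loss fraction.
#' @param max_days_to_join_curve Latest day to join the first curve.
#' @param p_single_curve Probability of following a single curve.
#' @param p_three_plus_curves Probability of following >= 3 curves.
#' @param fall_magnitude Range (lo, hi) of the fractional P0 drop per
#'   fall.
#' @param fall_min_gap_days Minimum days between successive falls.
#' @param noise_sd_log SD of multiplicative measurement noise on the ln
#'   scale; 0 for noise-free series.
#' @param scale_quantum_g Scale resolution in grams (0 = no rounding).
#' @param coeffs Global [growth_coefficients()].
#' @param n_days Last measurement day (series runs day 0 to `n_days`).
#' @param sex_effect_b1 Additive shift of `b1` for males (default 0: no
#'   sex effect, as observed in the neonatal window); a hook for power
#'   studies of [compare_sex_growth_rates()].
#' @param seed Integer seed making [simulate_population()] fully
#'   reproducible.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(breeds = default_breed_table(),
                       p_gain_from_day0 = 0.48,
                       p_initial_loss = 0.33,
                       initial_loss_max = 0.20,
                       max_days_to_join_curve = 3,
                       p_single_curve = 0.10,
                       p_three_plus_curves = 0.67,
                       fall_magnitude = c(0.05, 0.15),
                       fall_min_gap_days = 3,
                       noise_sd_log = 0.026,
                       scale_quantum_g = 5,
                       coeffs = growth_coefficients(),
                       n_days = 21,
                       sex_effect_b1 = 0,
                       seed = NULL) {
  stopifnot(is.data.frame(breeds), nrow(breeds) >= 1L,
            all(c("name", "birth_weight_lo_g", "birth_weight_hi_g",
                  "litters", "litter_size_lo", "litter_size_hi") %in%
                  names(breeds)))
  if (any(breeds$birth_weight_lo_g <= 0) ||
      any(breeds$birth_weight_hi_g < breeds$birth_weight_lo_g)) {
    stop("breed birth-weight ranges must be positive and ordered",
         call. = FALSE)
  }
  probs <- c(p_gain_from_day0, p_initial_loss, p_single_curve,
             p_three_plus_curves)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_gain_from_day0 + p_initial_loss > 1) {
    stop("p_gain_from_day0 + p_initial_loss must not exceed 1",
         call. = FALSE)
  }
  if (p_single_curve + p_three_plus_curves > 1) {
    stop("p_single_curve + p_three_plus_curves must not exceed 1",
         call. = FALSE)
  }
  stopifnot(length(fall_magnitude) == 2L, fall_magnitude[1L] > 0,
            fall_magnitude[2L] < 1, fall_magnitude[1L] <= fall_magnitude[2L],
            initial_loss_max >= 0, initial_loss_max < 1,
            scale_quantum_g >= 0, noise_sd_log >= 0,
            n_days >= 7, fall_min_gap_days >= 1,
            max_days_to_join_curve >= 1)
  structure(list(
    breeds = breeds,
    p_gain_from_day0 = p_gain_from_day0,
    p_initial_loss = p_initial_loss,
    initial_loss_max = initial_loss_max,
    max_days_to_join_curve = max_days_to_join_curve,
    p_single_curve = p_single_curve,
    p_three_plus_curves = p_three_plus_curves,
    fall_magnitude = fall_magnitude,
    fall_min_gap_days = fall_min_gap_days,
    noise_sd_log = noise_sd_log,
    scale_quantum_g = scale_quantum_g,
    coeffs = as_growth_coefficients(coeffs),
    n_days = as.integer(n_days),
    sex_effect_b1 = sex_effect_b1,
    seed = seed), class = "sim_config")
}

runif_int <- function(n, lo, hi) {
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

# Number of curves for one puppy: 1 with p_single; >= 3 with
# p_three_plus; otherwise 2. Among >=3, four curves occur a quarter of
# the time (the window rarely accommodates more).
draw_n_curves <- function(config) {
  u <- stats::runif(1)
  if (u < config$p_single_curve) return(1L)
  if (u < config$p_single_curve + (1 - config$p_single_curve -
                                   config$p_three_plus_curves)) return(2L)
  if (stats::runif(1) < 0.25) 4L else 3L
}

#' Simulate one puppy's weight series
#'
#' Draws the puppy's growth-pattern class (number of curves), its
#' initial phase (day-0 gainer, brief stagnation, or loss of
#' U(0, `initial_loss_max`) over the first 1-2 days followed by joining
#' a curve within `max_days_to_join_curve` days), fall times with the
#' configured separation and 1-2 off-curve transition days each, and
#' fall magnitudes from the configured range; generates clean weights
#' from the growth law per segment, then applies multiplicative ln-
#' scale noise and scale quantization. Uses the current RNG state;
#' seed via [simulate_population()] or `set.seed()` for
#' reproducibility.
#'
#' @param birth_weight_g Birth weight in grams (> 0).
#' @param config A [sim_config()].
#' @param sex `"male"`, `"female"` or `"unknown"` (only used by the
#'   `sex_effect_b1` hook).
#' @return A list (`sim_puppy`): `records` (data.frame `day,
#'   weight_g`), and `truth` with `segments` (`start_day, end_day,
#'   p0_g`), `off_curve_days`, `fall_days`, `n_curves`,
#'   `gained_from_day0`, `initial_loss_fraction`, `join_day`,
#'   `clean_weight_g`.
#' @export
simulate_puppy <- function(birth_weight_g, config = sim_config(),
                           sex = "unknown") {
  stopifnot(inherits(config, "sim_config"))
  check_p0(birth_weight_g, "birth_weight_g")
  coeffs <- config$coeffs
  if (sex == "male" && config$sex_effect_b1 != 0) {
    coeffs <- growth_coefficients(coeffs$b1 + config$sex_effect_b1,
                                  coeffs$b2)
  }
  n_days <- config$n_days
  days <- 0:n_days

  # --- initial phase -------------------------------------------------
  u <- stats::runif(1)
  if (u < config$p_gain_from_day0) {
    loss <- 0; loss_days <- 0L; join_day <- 0L
    gained <- TRUE
  } else {
    gained <- FALSE
    loss_days <- runif_int(1, 1L, 2L)
    loss <- if (u < config$p_gain_from_day0 + config$p_initial_loss) {
      stats::runif(1, 0, config$initial_loss_max)
    } else 0   # stagnation: no gain, no measurable loss
    join_day <- runif_int(1, loss_days,
                          max(loss_days, config$max_days_to_join_curve))
  }

  # --- curve sequence ------------------------------------------------
  n_curves <- draw_n_curves(config)
  n_falls <- n_curves - 1L
  # each fall needs its transition (1-2 days), >= 2 on-curve points
  # before the next fall, and >= 3 points after the last one
  transitions <- if (n_falls > 0) runif_int(n_falls, 1L, 2L) else integer()
  step_req <- pmax(config$fall_min_gap_days, transitions + 2L)
  fall_days <- integer(n_falls)
  prev <- join_day
  feasible <- TRUE
  for (k in seq_len(n_falls)) {
    lo <- prev + step_req[k]
    hi <- n_days - 2L - if (k < n_falls) sum(step_req[(k + 1L):n_falls]) else 0L
    if (lo > hi) { feasible <- FALSE; break }
    fall_days[k] <- runif_int(1, lo, hi)
    prev <- fall_days[k]
  }
  if (!feasible) {
    # window too short for the drawn pattern: drop the excess falls
    keep <- seq_len(k - 1L)
    fall_days <- fall_days[keep]
    transitions <- transitions[keep]
    n_falls <- length(fall_days)
    n_curves <- n_falls + 1L
  }
  magnitudes <- if (n_falls > 0) {
    stats::runif(n_falls, config$fall_magnitude[1L], config$fall_magnitude[2L])
  } else numeric()

  # --- clean weights -------------------------------------------------
  first_p0 <- if (gained) birth_weight_g else {
    birth_weight_g * setback_adjusted_p0(1 - loss, join_day, coeffs)
  }
  p0_seq <- first_p0 * cumprod(c(1, 1 - magnitudes))
  seg_start <- c(join_day, fall_days)
  seg_end <- c(fall_days - transitions - 1L, n_days)

  g <- growth_factor(days, coeffs)
  clean <- numeric(length(days))
  off_curve <- logical(length(days))

  if (!gained) {
    # descent to the loss bottom, then flat until the curve is joined
    bottom <- birth_weight_g * (1 - loss)
    for (d in 0:(join_day - 1L)) {
      frac <- if (loss_days > 0) min(d / loss_days, 1) else 1
      clean[d + 1L] <- exp((1 - frac) * log(birth_weight_g) +
                             frac * log(bottom))
      off_curve[d + 1L] <- TRUE
    }
  }
  for (s in seq_len(n_curves)) {
    idx <- which(days >= seg_start[s] & days <= seg_end[s])
    clean[idx] <- p0_seq[s] * g[idx]
  }
  for (k in seq_len(n_falls)) {
    trans_days <- (fall_days[k] - transitions[k]):(fall_days[k] - 1L)
    for (d in trans_days) {
      frac <- (d - (fall_days[k] - transitions[k]) + 1) / (transitions[k] + 1)
      clean[d + 1L] <- exp((1 - frac) * log(p0_seq[k] * g[d + 1L]) +
                             frac * log(p0_seq[k + 1L] * g[d + 1L]))
      off_curve[d + 1L] <- TRUE
    }
  }

  # --- noise and quantization ---------------------------------------
  w <- clean
  if (config$noise_sd_log > 0) {
    w <- w * exp(stats::rnorm(length(w), 0, config$noise_sd_log))
  }
  if (config$scale_quantum_g > 0) {
    w <- pmax(round(w / config$scale_quantum_g) * config$scale_quantum_g,
              config$scale_quantum_g)
  }

  list(records = data.frame(day = days, weight_g = w),
       truth = list(
         segments = data.frame(start_day = seg_start, end_day = seg_end,
                               p0_g = p0_seq),
         off_curve_days = days[off_curve],
         fall_days = fall_days,
         n_curves = n_curves,
         gained_from_day0 = gained,
         initial_loss_fraction = loss,
         join_day = join_day,
         clean_weight_g = clean))
}

#' Simulate a multi-breed population of weight series
#'
#' For each breed in the configuration, draws its litters and litter
#' sizes, uniform birth weights within the breed range and
#' Bernoulli(0.5) sexes, and simulates each puppy with
#' [simulate_puppy()]. Fully reproducible from `config$seed` (or the
#' `seed` argument).
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return An object of class `puppy_dataset`: `records` (long-format
#'   weight records), `truth` (named per-puppy ground-truth list) and
#'   `config`.
#' @export
simulate_population <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  rec_list <- list()
  truth <- list()
  for (b in seq_len(nrow(config$breeds))) {
    br <- config$breeds[b, ]
    code <- toupper(gsub("[^A-Za-z]", "", abbreviate(br$name, 4)))
    for (l in seq_len(br$litters)) {
      size <- runif_int(1, br$litter_size_lo, br$litter_size_hi)
      litter_id <- sprintf("%s-L%02d", code, l)
      for (p in seq_len(size)) {
        bw <- stats::runif(1, br$birth_weight_lo_g, br$birth_weight_hi_g)
        sex <- if (stats::runif(1) < 0.5) "male" else "female"
        pid <- sprintf("%s-P%02d", litter_id, p)
        pup <- simulate_puppy(bw, config, sex)
        rec_list[[pid]] <- data.frame(
          puppy_id = pid, litter_id = litter_id, breed = br$name, sex = sex,
          day = pup$records$day, weight_g = pup$records$weight_g,
          stringsAsFactors = FALSE)
        pup$truth$birth_weight_g <- bw
        truth[[pid]] <- pup$truth
      }
    }
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  structure(list(records = validate_records(records), truth = truth,
                 config = config),
            class = "puppy_dataset")
}

#' @export
print.puppy_dataset <- function(x, ...) {
  cat(sprintf("Simulated puppy dataset: %d puppies, %d breeds, %d records\n",
              length(x$truth), length(unique(x$records$breed)),
              nrow(x$records)))
  invisible(x)
}

#' Ground-truth pattern proportions of a simulated dataset
#'
#' The generator-side analogue of [population_summary()]: proportions
#' computed from the truth registry rather than from recovered
#' trajectories, used to check that the generator realises its
#' configured pattern probabilities.
#'
#' @param dataset A `puppy_dataset` from [simulate_population()].
#' @return A list: `n`, `frac_single_curve`, `frac_three_plus_curves`,
#'   `frac_gained_from_day0`, `frac_joined_within_3_days`.
#' @export
truth_pattern_summary <- function(dataset) {
  stopifnot(inherits(dataset, "puppy_dataset"))
  tr <- dataset$truth
  n_curves <- vapply(tr, function(t) t$n_curves, integer(1))
  gained <- vapply(tr, function(t) t$gained_from_day0, logical(1))
  join <- vapply(tr, function(t) t$join_day, numeric(1))
  list(n = length(tr),
       frac_single_curve = mean(n_curves == 1L),
       frac_three_plus_curves = mean(n_curves >= 3L),
       frac_gained_from_day0 = mean(gained),
       frac_joined_within_3_days = if (any(!gained)) {
         mean(join[!gained] <= 3)
       } else NA_real_)
}
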