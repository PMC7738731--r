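# Fixture builders shared across the suite. Everything is generated in
# code; no stored data files.

published <- growth_coefficients()

# Long-format records for puppies growing exactly on the model curve.
exact_records <- function(p0s, days = 0:21, breed = "Old English Sheepdog",
                          sexes = NULL) {
  if (is.null(sexes)) {
    sexes <- rep(c("male", "female"), length.out = length(p0s))
  }
  do.call(rbind, lapply(seq_along(p0s), function(i) {
    data.frame(puppy_id = sprintf("P%02d", i), litter_id = "L01",
               breed = breed, sex = sexes[i], day = days,
               weight_g = predict_weight(p0s[i], days),
               stringsAsFactors = FALSE)
  }))
}

# One puppy's series following curve p0_a up to `last_a`, curve p0_b
# from `first_b`, with the days between interpolated in log space at
# the given fractions (positions between the two curves).
two_curve_series <- function(p0_a, p0_b, last_a, first_b,
                             fractions, days = 0:21,
                             coeffs = published) {
  g <- exp(coeffs$b1 * days - coeffs$b2 * days^2)
  w <- ifelse(days <= last_a, p0_a * g, p0_b * g)
  gap_days <- (last_a + 1):(first_b - 1)
  w[gap_days + 1] <- exp((1 - fractions) * log(p0_a * g[gap_days + 1]) +
                           fractions * log(p0_b * g[gap_days + 1]))
  data.frame(day = days, weight_g = w)
}

# Independent straight-loop metric oracles.
loop_mare <- function(obs, pred) {
  tot <- 0
  for (i in seq_along(obs)) tot <- tot + abs(obs[i] - pred[i]) / pred[i]
  tot / length(obs)
}
loop_rmse <- function(obs, pred) {
  tot <- 0
  for (i in seq_along(obs)) tot <- tot + (obs[i] - pred[i])^2
  sqrt(tot / length(obs))
}
loop_origin <- function(obs, pred) {
  sxy <- 0; sxx <- 0
  for (i in seq_along(obs)) {
    sxy <- sxy + obs[i] * pred[i]
    sxx <- sxx + obs[i]^2
  }
  a <- sxy / sxx
  sse <- 0; syy <- 0
  for (i in seq_along(obs)) {
    sse <- sse + (pred[i] - a * obs[i])^2
    syy <- syy + pred[i]^2
  }
  list(slope = a, r2 = 1 - sse / syy)
}
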