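test_that("curve-offset least squares matches its closed form and oracle", {
  s <- data.frame(day = 0:10, weight_g = predict_weight(300, 0:10))
  expect_equal(estimate_p0(s), 300, tolerance = 1e-10)

  # frozen value computed with an independent 1-D grid-search minimizer
  two <- data.frame(day = 0:1, weight_g = c(100, 120))
  expect_equal(estimate_p0(two), 103.0770, tolerance = 1e-3)

  # linearity: scaling the series scales the estimate
  expect_equal(estimate_p0(transform(two, weight_g = 3 * weight_g)),
               3 * estimate_p0(two), tolerance = 1e-12)

  # random small instances against a grid-search oracle
  for (s_i in 1:5) {
    set.seed(40 + s_i)
    days <- sort(sample(0:21, 6))
    w <- predict_weight(runif(1, 100, 600), days) * exp(rnorm(6, 0, 0.05))
    grid <- seq(50, 900, by = 0.01)
    g <- exp(0.13084 * days - 0.001616 * days^2)
    sse <- vapply(grid, function(p) sum((w - p * g)^2), numeric(1))
    est <- estimate_p0(data.frame(day = days, weight_g = w))
    expect_equal(est, grid[which.min(sse)], tolerance = 1e-5 * est)
  }
  expect_error(estimate_p0(data.frame(day = 1, weight_g = 100)),
               "at least 2")
})

test_that("an exact single-curve series yields one segment", {
  s <- data.frame(day = 0:21, weight_g = predict_weight(403, 0:21))
  traj <- segment_trajectory(s)
  expect_identical(traj$n_curves, 1L)
  expect_identical(traj$pattern, "single_curve")
  expect_equal(traj$segments$p0_g, 403, tolerance = 1e-9)
  expect_true(traj$gained_from_day0)
  expect_identical(traj$days_to_first_curve, 0L)
})

test_that("a simulated fall is recovered with its transition days off-curve", {
  s <- two_curve_series(250, 230, last_a = 9, first_b = 12,
                        fractions = c(0.45, 0.55))
  traj <- segment_trajectory(s)
  expect_identical(traj$n_curves, 2L)
  expect_equal(traj$segments$p0_g, c(250, 230), tolerance = 1e-6)
  expect_identical(sort(traj$off_curve_days), c(10L, 11L))
  expect_identical(traj$segments$start_day, c(0L, 12L))
})

test_that("oscillation inside the threshold stays on one curve", {
  set.seed(5)
  w <- predict_weight(300, 0:21) * exp(runif(22, -0.01, 0.01))
  traj <- segment_trajectory(data.frame(day = 0:21, weight_g = w))
  expect_identical(traj$n_curves, 1L)
})

test_that("segment P0 sequence is strictly decreasing on noisy output", {
  cfg <- sim_config(seed = NULL)
  for (s in 1:25) {
    set.seed(500 + s)
    pup <- simulate_puppy(runif(1, 150, 800), cfg)
    traj <- try(segment_trajectory(pup$records), silent = TRUE)
    if (inherits(traj, "try-error")) next
    expect_true(all(diff(traj$segments$p0_g) < 0))
    # every record is in exactly one segment or off-curve
    a <- traj$assignments
    expect_identical(nrow(a), nrow(pup$records))
    expect_identical(sum(!is.na(a$segment)) + length(traj$off_curve_days),
                     nrow(a))
  }
})

test_that("re-segmenting the fitted predictions reproduces the segments", {
  s <- two_curve_series(400, 352, last_a = 8, first_b = 11,
                        fractions = c(0.45, 0.55))
  traj <- segment_trajectory(s)
  on_curve <- traj$assignments[!is.na(traj$assignments$segment), ]
  again <- segment_trajectory(data.frame(day = on_curve$day,
                                         weight_g = on_curve$predicted_g))
  expect_identical(again$n_curves, traj$n_curves)
  expect_equal(again$segments$p0_g, traj$segments$p0_g, tolerance = 1e-9)
})

test_that("pattern classification reports the initial phase", {
  # 20% loss by day 2, joining the implied setback curve at day 3
  w0 <- 500
  days <- 0:21
  p0 <- w0 * setback_adjusted_p0(0.8, 3)
  w <- predict_weight(p0, days)
  w[1:3] <- c(w0, w0 * 0.9, w0 * 0.8)   # loss path, off any curve
  traj <- segment_trajectory(data.frame(day = days, weight_g = w))
  cls <- classify_pattern(traj)
  expect_false(cls$gained_from_day0)
  expect_equal(cls$initial_loss_fraction, 0.8)
  expect_identical(cls$days_to_first_curve, 3L)
  expect_identical(sort(traj$off_curve_days), 0:2)

  single <- segment_trajectory(
    data.frame(day = days, weight_g = predict_weight(300, days)))
  cls2 <- classify_pattern(single)
  expect_true(cls2$gained_from_day0)
  expect_identical(cls2$days_to_first_curve, 0L)
  expect_true(is.na(cls2$initial_loss_fraction))
})

test_that("population summary counts pattern fractions", {
  mk <- function(p0s, falls) {
    if (falls == 0) {
      s <- data.frame(day = 0:21, weight_g = predict_weight(p0s, 0:21))
    } else {
      s <- two_curve_series(p0s, p0s * 0.85, last_a = 8, first_b = 11,
                            fractions = c(0.45, 0.55))
    }
    segment_trajectory(s)
  }
  trajs <- c(lapply(c(200), mk, falls = 0),
             lapply(c(300, 400, 500, 600, 700, 800, 250, 350, 450), mk,
                    falls = 1))
  ps <- population_summary(trajs)
  expect_identical(ps$n, 10L)
  expect_equal(ps$frac_single_curve, 0.10)
  expect_equal(ps$frac_three_plus_curves, 0)
  expect_error(population_summary(list()), "at least one")
})

test_that("noise-free fall recovery is exact across seeded trajectories", {
  cfg <- sim_config(p_gain_from_day0 = 1, p_initial_loss = 0,
                    fall_magnitude = c(0.05, 0.15), fall_min_gap_days = 4,
                    noise_sd_log = 0, scale_quantum_g = 0)
  for (s in 1:30) {
    set.seed(700 + s)
    pup <- simulate_puppy(runif(1, 250, 500), cfg)
    traj <- segment_trajectory(pup$records)
    expect_identical(traj$n_curves, pup$truth$n_curves)
    expect_true(all(abs(traj$segments$p0_g /
                          pup$truth$segments$p0_g - 1) < 0.01))
  }
})
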