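test_that("simulator configuration validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(p_single_curve = 1.2), "0, 1")
  expect_error(sim_config(p_single_curve = 0.6, p_three_plus_curves = 0.6),
               "exceed")
  expect_error(sim_config(fall_magnitude = c(0.2, 0.1)))
  bad <- default_breed_table()
  bad$birth_weight_hi_g[1] <- 10
  expect_error(sim_config(breeds = bad), "ordered")
})

test_that("a forced single-curve noise-free puppy closes the loop", {
  cfg <- sim_config(p_single_curve = 1, p_three_plus_curves = 0,
                    p_gain_from_day0 = 1, p_initial_loss = 0,
                    noise_sd_log = 0, scale_quantum_g = 0)
  set.seed(1)
  pup <- simulate_puppy(320, cfg)
  expect_identical(pup$truth$n_curves, 1L)
  expect_equal(pup$records$weight_g, predict_weight(320, 0:21),
               tolerance = 1e-12)
  traj <- segment_trajectory(pup$records)
  expect_equal(traj$segments$p0_g, 320, tolerance = 1e-9)
})

test_that("a forced full initial loss lands on the setback curve", {
  cfg <- sim_config(p_gain_from_day0 = 0, p_initial_loss = 1,
                    initial_loss_max = 0.20, p_single_curve = 1,
                    p_three_plus_curves = 0, noise_sd_log = 0,
                    scale_quantum_g = 0)
  set.seed(8)
  pup <- simulate_puppy(500, cfg)
  tr <- pup$truth
  expect_false(tr$gained_from_day0)
  expect_lte(tr$join_day, cfg$max_days_to_join_curve)
  # the first curve passes through the retained weight at the join day
  expect_equal(tr$segments$p0_g[1],
               500 * setback_adjusted_p0(1 - tr$initial_loss_fraction,
                                         tr$join_day),
               tolerance = 1e-9)
})

test_that("quantization rounds every weight to the scale division", {
  cfg <- sim_config(scale_quantum_g = 5)
  set.seed(3)
  pup <- simulate_puppy(400, cfg)
  expect_true(all(pup$records$weight_g %% 5 == 0))
})

test_that("truth registry is internally consistent", {
  cfg <- sim_config()
  for (s in 1:20) {
    set.seed(900 + s)
    pup <- simulate_puppy(runif(1, 70, 1000), cfg)
    tr <- pup$truth
    expect_identical(nrow(tr$segments), tr$n_curves)
    expect_true(all(diff(tr$segments$p0_g) < 0) || tr$n_curves == 1L)
    expect_true(all(diff(tr$fall_days) >= cfg$fall_min_gap_days) ||
                  length(tr$fall_days) < 2L)
    # clean weights sit exactly on the truth curves over segment spans
    for (k in seq_len(tr$n_curves)) {
      days <- tr$segments$start_day[k]:tr$segments$end_day[k]
      expect_equal(tr$clean_weight_g[days + 1],
                   predict_weight(tr$segments$p0_g[k], days),
                   tolerance = 1e-9)
    }
  }
})

test_that("population simulation is reproducible and respects breed ranges", {
  cfg <- sim_config(seed = 42)
  ds1 <- simulate_population(cfg)
  ds2 <- simulate_population(cfg)
  expect_identical(ds1$records, ds2$records)
  ds3 <- simulate_population(cfg, seed = 43)
  expect_false(identical(ds1$records, ds3$records))

  expect_true(all(ds1$records$weight_g > 0))
  day0 <- ds1$records[ds1$records$day == 0, ]
  tab <- default_breed_table()
  for (b in seq_len(nrow(tab))) {
    w0 <- day0$weight_g[day0$breed == tab$name[b]]
    # day-0 weights stay within the breed range up to noise and the
    # 5-g scale division
    lo <- tab$birth_weight_lo_g[b] * exp(-4 * cfg$noise_sd_log) - 2.5
    hi <- tab$birth_weight_hi_g[b] * exp(4 * cfg$noise_sd_log) + 2.5
    expect_true(all(w0 >= lo & w0 <= hi))
  }
  # all birth weights within the overall range
  bw <- vapply(ds1$truth, function(t) t$birth_weight_g, numeric(1))
  expect_true(all(bw >= 70 & bw <= 1000))
})

test_that("configured pattern proportions are realised at n = 400", {
  breeds <- data.frame(name = "Generic", birth_weight_lo_g = 200,
                       birth_weight_hi_g = 600, litters = 80,
                       litter_size_lo = 5, litter_size_hi = 5)
  cfg <- sim_config(breeds = breeds, seed = 123)
  ds <- simulate_population(cfg)
  ts <- truth_pattern_summary(ds)
  expect_identical(ts$n, 400L)
  ci <- function(p) stats::qbinom(c(0.025, 0.975), ts$n, p) / ts$n
  expect_true(ts$frac_gained_from_day0 >= ci(0.48)[1] &&
                ts$frac_gained_from_day0 <= ci(0.48)[2])
  expect_true(ts$frac_single_curve >= ci(0.10)[1] &&
                ts$frac_single_curve <= ci(0.10)[2])
  expect_true(ts$frac_three_plus_curves >= ci(0.67)[1] &&
                ts$frac_three_plus_curves <= ci(0.67)[2])
  expect_gte(ts$frac_joined_within_3_days, 0.95)
})

test_that("noisy series deviate from clean curves at the configured scale", {
  cfg <- sim_config(scale_quantum_g = 0)
  set.seed(11)
  devs <- c()
  while (length(devs) < 5000) {
    pup <- simulate_puppy(runif(1, 200, 800), cfg)
    devs <- c(devs, abs(log(pup$records$weight_g) -
                          log(pup$truth$clean_weight_g)))
  }
  # E|eps| for Gaussian ln-noise is sigma * sqrt(2/pi)
  expect_equal(mean(devs), 0.026 * sqrt(2 / pi), tolerance = 0.2)
})

test_that("dataset CSV export and load round-trip exactly", {
  ds <- simulate_population(sim_config(seed = 5,
    breeds = default_breed_table()[c(1, 19), ]))
  path <- withr::local_tempfile(fileext = ".csv")
  export_dataset(ds$records, path)
  back <- load_dataset(path)
  expect_equal(back$weight_g, ds$records$weight_g)
  expect_identical(back$puppy_id, ds$records$puppy_id)
  expect_identical(back$day, ds$records$day)
})

test_that("malformed dataset files are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("puppy_id,litter_id,breed,sex,day,weight_g",
               "a,l,b,male,0,100",
               "a,l,b,male,1,0"), path)
  expect_error(load_dataset(path), "line 3.*non-positive")
  writeLines(c("puppy_id,litter_id,breed,sex,day,weight_g",
               "a,l,b,male,0,100",
               "a,l,b,male"), path)
  expect_error(load_dataset(path), "line 3")
  writeLines(c("puppy_id,litter_id,breed,sex,day,weight_g",
               "a,l,b,male,0,100",
               "a,l,b,male,0,105"), path)
  expect_error(load_dataset(path), "duplicate")
  writeLines(c("puppy_id,litter_id,breed,sex,day,weight_g",
               "a,l,b,male,zero,100"), path)
  expect_error(load_dataset(path), "non-numeric day")
})
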