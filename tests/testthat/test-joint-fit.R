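test_that("design matrix has indicator block plus polynomial age columns", {
  recs <- exact_records(c(200, 300), days = 0:2)
  d <- build_design_matrix(recs, 2)
  expect_identical(dim(d$X), c(6L, 4L))
  expect_true(all(rowSums(d$X[, 1:2]) == 1))
  expect_equal(d$y, log(recs$weight_g[order(recs$puppy_id, recs$day)]))
  row_b3 <- which(recs$puppy_id == "P02" & recs$day == 2)
  expect_equal(unname(d$X[row_b3, ]), c(0, 1, 2, 4))
  # column count is n_puppies + order
  expect_identical(ncol(build_design_matrix(exact_records(c(1, 2, 3) * 100,
                                                          0:4), 3)$X), 6L)
  expect_error(build_design_matrix(exact_records(150, days = 0:1), 2),
               "at least 3")
})

test_that("shared-slope fit recovers generating coefficients exactly", {
  p0s <- c(150, 250, 350, 450, 600)
  recs <- exact_records(p0s)
  fit <- fit_shared_slope_model(recs, 2)
  expect_equal(fit$coefficients$estimate[1], 0.13084, tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate[2], -0.001616, tolerance = 1e-10)
  expect_equal(fit$intercepts$a, log(p0s), tolerance = 1e-10)
  expect_equal(fit$intercepts$p0_g, p0s, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lte(fit$adj_r2, fit$r2)
  expect_s3_class(fit$coeffs, "growth_coefficients")
})

test_that("tiny instance matches an independent normal-equations solver", {
  recs <- exact_records(c(180, 420), days = 0:3)
  set.seed(4)
  recs$weight_g <- recs$weight_g * exp(rnorm(nrow(recs), 0, 0.05))
  fit <- fit_shared_slope_model(recs, 1)
  X <- cbind(recs$puppy_id == "P01", recs$puppy_id == "P02", recs$day) * 1
  beta <- solve(t(X) %*% X, t(X) %*% log(recs$weight_g))
  expect_equal(fit$intercepts$a, beta[1:2], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fit$coefficients$estimate[1], beta[3], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("fit is invariant to record order and id relabeling", {
  recs <- exact_records(c(150, 250, 350))
  set.seed(9)
  recs$weight_g <- recs$weight_g * exp(rnorm(nrow(recs), 0, 0.03))
  fit1 <- fit_shared_slope_model(recs, 2)
  shuffled <- recs[sample(nrow(recs)), ]
  fit2 <- fit_shared_slope_model(shuffled, 2)
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-12)
  expect_equal(fit1$intercepts, fit2$intercepts, tolerance = 1e-12)
  relabeled <- recs
  relabeled$puppy_id <- chartr("123", "ZYX", relabeled$puppy_id)
  fit3 <- fit_shared_slope_model(relabeled, 2)
  expect_equal(sort(fit3$intercepts$a), sort(fit1$intercepts$a),
               tolerance = 1e-12)
  expect_equal(fit3$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-12)
})

test_that("scaling one puppy's weights shifts only its intercept", {
  recs <- exact_records(c(150, 250, 350))
  set.seed(2)
  recs$weight_g <- recs$weight_g * exp(rnorm(nrow(recs), 0, 0.02))
  fit1 <- fit_shared_slope_model(recs, 2)
  bumped <- recs
  sel <- bumped$puppy_id == "P02"
  bumped$weight_g[sel] <- bumped$weight_g[sel] * exp(0.25)
  fit2 <- fit_shared_slope_model(bumped, 2)
  delta <- fit2$intercepts$a - fit1$intercepts$a
  expect_equal(delta[2], 0.25, tolerance = 1e-10)
  expect_equal(delta[-2], c(0, 0), tolerance = 1e-10)
  expect_equal(fit2$coefficients$estimate, fit1$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("true coefficients fall inside the 95% CIs at nominal rate", {
  p0s <- c(150, 200, 250, 300, 350, 400, 450, 500, 550, 600, 650, 700,
           750, 800)
  base <- exact_records(p0s)
  hits <- 0
  n_rep <- 40
  for (s in seq_len(n_rep)) {
    set.seed(1000 + s)
    recs <- base
    recs$weight_g <- recs$weight_g * exp(rnorm(nrow(recs), 0, 0.048))
    ct <- fit_shared_slope_model(recs, 2)$coefficients
    hits <- hits + (ct$ci_lo[1] <= 0.13084 && 0.13084 <= ct$ci_hi[1] &&
                      ct$ci_lo[2] <= -0.001616 && -0.001616 <= ct$ci_hi[2])
  }
  expect_gte(hits, 0.9 * n_rep)
})

test_that("order selection keeps the quadratic and drops higher orders", {
  recs <- exact_records(c(150, 250, 350, 450, 600))
  sel <- select_order(recs)
  expect_identical(sel$order, 2L)
  cmp <- sel$order_comparison
  expect_false(any(cmp$all_significant[cmp$order > 2]))
  expect_identical(select_order(recs, max_order = 1)$order, 1L)
})

test_that("order selection picks the linear model for pure exponential data", {
  recs <- exact_records(c(150, 250, 350, 450, 600))
  set.seed(7)
  recs$weight_g <- exp(log(rep(c(150, 250, 350, 450, 600), each = 22)) +
                         0.13084 * recs$day + rnorm(nrow(recs), 0, 0.03))
  expect_identical(select_order(recs)$order, 1L)
})

test_that("residual diagnostics flag constructed autocorrelation only", {
  recs <- exact_records(c(150, 250, 350, 450))
  fit <- fit_shared_slope_model(recs, 2)
  dg <- residual_diagnostics(fit, recs)
  expect_false(any(dg$autocorrelation$flagged))
  expect_equal(dg$by_sex$mean_residual, c(0, 0), tolerance = 1e-12)

  # exact alternating residuals give lag-1 autocorrelation near -1
  alt <- fit
  m <- sum(alt$residuals$puppy_id == "P01")
  alt$residuals$residual[alt$residuals$puppy_id == "P01"] <-
    rep(c(0.05, -0.05), length.out = m)
  dg2 <- residual_diagnostics(alt, recs)
  row <- dg2$autocorrelation[dg2$autocorrelation$puppy_id == "P01", ]
  expect_lt(row$lag1, -0.9)
  expect_true(row$flagged)

  # i.i.d.-noise simulation keeps the flag rate near nominal
  flagged <- 0; total <- 0
  for (s in 1:25) {
    set.seed(200 + s)
    rn <- recs
    rn$weight_g <- rn$weight_g * exp(rnorm(nrow(rn), 0, 0.04))
    dn <- residual_diagnostics(fit_shared_slope_model(rn, 2), rn)
    flagged <- flagged + sum(dn$autocorrelation$flagged)
    total <- total + nrow(dn$autocorrelation)
  }
  expect_lte(flagged / total, 0.10)
})

test_that("sex comparison is null for mirrored groups and errors when starved", {
  recs <- exact_records(c(150, 250, 350))
  both <- rbind(transform(recs, puppy_id = paste0(puppy_id, "m"),
                          sex = "male"),
                transform(recs, puppy_id = paste0(puppy_id, "f"),
                          sex = "female"))
  cmp <- compare_sex_growth_rates(both)
  expect_equal(cmp$t, 0)
  expect_equal(cmp$p, 1)
  expect_error(
    compare_sex_growth_rates(exact_records(c(150, 250),
                                           sexes = c("male", "female"))),
    "at least 2")
})

test_that("null sex-difference p-values are approximately uniform", {
  # equal group means, unequal spreads, balanced sizes: the pooled t
  # test stays close to its nominal null
  n_rep <- 200
  pvals <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    set.seed(3000 + s)
    rates <- c(rnorm(12, 0.11, 0.01), rnorm(12, 0.11, 0.03))
    sex <- rep(c("male", "female"), each = 12)
    recs <- do.call(rbind, lapply(seq_along(rates), function(i) {
      data.frame(puppy_id = sprintf("Q%02d", i), litter_id = "L1",
                 breed = "b", sex = sex[i], day = 0:1,
                 weight_g = 300 * c(1, 1 + rates[i]))
    }))
    pvals[s] <- compare_sex_growth_rates(recs)$p
  }
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
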