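test_that("deviation summaries match per-pair hand computation", {
  d <- deviation_summary(predicted = 5, measured = 4)
  expect_equal(d$ad_mean, 1)
  expect_equal(d$rd_mean, 25)

  perfect <- deviation_summary(c(2, 3, 4), c(2, 3, 4))
  expect_equal(perfect$ad_mean, 0)
  expect_equal(perfect$ad_sd, 0)
  expect_equal(perfect$rd_mean, 0)

  pred <- c(5.0, 2.0, 9.5); meas <- c(4.0, 2.5, 10.0)
  d3 <- deviation_summary(pred, meas)
  ad <- c(abs(5 - 4), abs(2 - 2.5), abs(9.5 - 10))
  rd <- ad / meas * 100
  expect_equal(d3$ad_mean, mean(ad))
  expect_equal(d3$ad_sd, sqrt(sum((ad - mean(ad))^2) / 2))
  expect_equal(d3$rd_mean, mean(rd))
  expect_equal(d3$rd_sd, sqrt(sum((rd - mean(rd))^2) / 2))

  # AD ignores the sign of the error; RD is scale-invariant
  expect_equal(deviation_summary(meas + 1, meas)$ad_mean,
               deviation_summary(meas - 1, meas)$ad_mean)
  expect_equal(deviation_summary(10 * pred, 10 * meas)$rd_mean, d3$rd_mean)

  expect_error(deviation_summary(1:3, 1:2), "same length")
  expect_error(deviation_summary(c(1, 2), c(1, 0)), "non-positive")
})

test_that("pearson_r enforces its preconditions and hits exact cases", {
  x <- c(1, 4, 2, 8)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -2 * x + 7), -1)
  expect_error(pearson_r(x, rep(3, 4)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("ICC(2,1) matches a from-scratch mean-squares oracle", {
  x <- c(9, 6, 8, 7, 10)
  y <- c(9.5, 6.2, 7.8, 7.1, 9.6)
  expect_equal(icc_agreement(x, y), icc21_oracle(x, y), tolerance = 1e-12)

  for (seed in 1:6) {
    set.seed(seed)
    a <- rnorm(7, 10, 3)
    b <- a + rnorm(7, 0.5, 1)
    expect_equal(icc_agreement(a, b), icc21_oracle(a, b), tolerance = 1e-10)
    expect_lte(icc_agreement(a, b), 1)
  }
})

test_that("ICC penalises systematic bias that Pearson's r cannot see", {
  x <- c(2, 5, 3, 8, 6)
  expect_equal(icc_agreement(x, x), 1, tolerance = 1e-12)
  shifted <- icc_agreement(x, x + 50)
  expect_equal(pearson_r(x, x + 50), 1)
  expect_lt(shifted, 0.1)

  deg <- icc_agreement(rep(4, 5), rep(4, 5))
  expect_equal(as.numeric(deg), 1)
  expect_true(attr(deg, "degenerate"))
})

test_that("Bland-Altman bias and limits follow the 2-SD definition", {
  perfect <- bland_altman(c(3, 4, 5), c(3, 4, 5))
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$loa_low, 0)
  expect_equal(perfect$loa_high, 0)
  expect_equal(perfect$outside_loa, 0)

  # differences (1, -1): zero bias, SD sqrt(2), limits at +/- 2 sqrt(2)
  ba <- bland_altman(c(11, 9), c(10, 10))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_high, 2 * sqrt(2))
  expect_equal(ba$loa_low, -2 * sqrt(2))

  const <- bland_altman(c(5, 6, 7), c(4, 5, 6))
  expect_equal(const$bias, 1)
  expect_equal(const$sd_diff, 0)
  expect_equal(const$outside_loa, 0)

  ba196 <- bland_altman(c(11, 9), c(10, 10), k_sd = 1.96)
  expect_equal(ba196$loa_high, 1.96 * sqrt(2))

  # under normal errors, +/- 2 SD limits cover about 95% of differences
  set.seed(4)
  m <- rnorm(2000, 50, 5)
  p <- m + rnorm(2000, 0, 2)
  cover <- bland_altman(m, p)
  expect_gt(1 - cover$outside_loa / cover$n, 0.93)
})

test_that("a perfect model validates perfectly on its own training data", {
  p0 <- noise_free_params(n = 6, seed = 19)
  sim <- simulate_study(p0)
  fit <- fit_met(sim$trials, "power")
  rep <- validate_met_model(fit, sim$trials)
  expect_equal(rep$deviation$ad_mean, 0, tolerance = 1e-9)
  expect_equal(rep$icc, 1, tolerance = 1e-9)
  expect_equal(rep$pearson_r, 1, tolerance = 1e-9)
  expect_equal(rep$bland_altman$bias, 0, tolerance = 1e-9)

  rr_fit <- fit_rr(sim$recovery, sim$trials)
  rec_rep <- validate_recovery_model(rr_fit, sim$recovery, sim$trials)
  expect_equal(rec_rep$deviation$ad_mean, 0, tolerance = 1e-9)
  expect_equal(rec_rep$bland_altman$outside_loa, 0)
})

test_that("external model functions validate through the same interface", {
  tr <- make_four_trials()
  oracle <- function(f) f^-1.15
  rep <- validate_met_model(oracle, tr, group_label = "all")
  fmvc <- tr$push_force_N / tr$mvc_N
  expect_equal(rep$table$predicted, fmvc^-1.15)
  expect_equal(rep$deviation$n, 4)
})

test_that("the correctly specified endurance form outpredicts a misspecified one", {
  # hold-out relative deviation, averaged over replicates: fitting the true
  # power form must beat deliberately fitting the exponential form
  rd <- vapply(1:40, function(i) {
    p <- generator_params(n_participants = 8, seed = 9000 + i)
    sim <- simulate_study(p)
    ab <- split_ab(sim$trials)
    pow <- validate_met_model(fit_met(ab$A, "power"), ab$B)
    expo <- validate_met_model(fit_met(ab$A, "exponential"), ab$B)
    c(pow$deviation$rd_mean, expo$deviation$rd_mean)
  }, numeric(2))
  expect_lt(mean(rd[1, ]), mean(rd[2, ]))
})
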