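test_that("the log transform of a recovery series behaves at its boundaries", {
  # no recovery yet: zero deficit reduction maps to y = 0
  tp <- transform_recovery(0:2, c(58.8, 58.8, 58.8), 100, 58.8)
  expect_equal(tp$y, c(0, 0))
  expect_equal(tp$t, 1:2)

  # arithmetic on a published mean trajectory point
  tp2 <- transform_recovery(c(0, 3), c(58.8, 73.9), 100, 58.8)
  expect_equal(tp2$y, log(41.2 / 26.1), tolerance = 1e-12)

  # an observation at MVC is excluded and counted, not an error
  tp3 <- transform_recovery(0:3, c(58.8, 66.2, 100, 73.9), 100, 58.8)
  expect_equal(attr(tp3, "excluded"), 1)
  expect_equal(nrow(tp3), 2)

  expect_error(transform_recovery(0:1, c(100, 100), 100, 100), "degenerate")
  expect_error(transform_recovery(0:1, c(50, 120), 100, 50),
               "no usable observations")
})

test_that("rate fitting on noise-free exponential data is exact", {
  for (rr_true in c(0.05, 0.132, 0.4, 1.1)) {
    p0 <- noise_free_params(n = 4, seed = round(rr_true * 100),
                            rr_true = rr_true)
    sim <- simulate_study(p0)
    fit <- fit_rr(sim$recovery, sim$trials)
    expect_equal(fit$rr, rr_true, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
    expect_equal(fit$excluded_points, 0)
  }
})

test_that("a single transformed point determines the rate directly", {
  mvc <- 100; ms0 <- 60; rr <- 0.132
  ms1 <- mvc - (mvc - ms0) * exp(-rr)  # y at t = 1 equals rr exactly
  tr <- data.frame(participant_id = "P01", push_force_N = 20, tool = "small",
                   tool_weight_kg = 1.5, mvc_N = mvc, met_min = 5,
                   ms0_N = ms0, cr10_0 = 8, stringsAsFactors = FALSE)
  rec <- data.frame(participant_id = "P01", push_force_N = 20, tool = "small",
                    t_min = c(0, 1), ms_N = c(ms0, ms1), cr10 = c(8, 6),
                    stringsAsFactors = FALSE)
  fit <- fit_rr(rec, tr)
  expect_equal(fit$rr, rr, tolerance = 1e-12)
  expect_equal(fit$n_points, 1)
})

test_that("the pooled slope matches the brute-force oracle and ignores order", {
  p <- generator_params(n_participants = 5, seed = 17)
  sim <- simulate_study(p)
  fit <- fit_rr(sim$recovery, sim$trials)

  tr <- sim$trials; rec <- sim$recovery
  ts <- c(); ys <- c()
  for (i in seq_len(nrow(tr))) {
    k <- paste(tr$participant_id[i], tr$push_force_N[i], tr$tool[i])
    s <- rec[paste(rec$participant_id, rec$push_force_N, rec$tool) == k &
               rec$t_min > 0, ]
    keep <- s$ms_N < tr$mvc_N[i]
    ts <- c(ts, s$t_min[keep])
    ys <- c(ys, log((tr$mvc_N[i] - tr$ms0_N[i]) /
                      (tr$mvc_N[i] - s$ms_N[keep])))
  }
  expect_equal(fit$rr, slope_origin_oracle(ts, ys), tolerance = 1e-12)
  expect_equal(fit$n_points, length(ts))

  shuffled <- sim$recovery[sample(nrow(sim$recovery)), ]
  expect_equal(fit_rr(shuffled, sim$trials)$rr, fit$rr, tolerance = 1e-12)
})

test_that("per-trial mode returns one diagnostic rate per trial", {
  p0 <- noise_free_params(n = 3, seed = 23)
  sim <- simulate_study(p0)
  fit <- fit_rr(sim$recovery, sim$trials, mode = "per_trial")
  expect_equal(nrow(fit$per_trial), nrow(sim$trials))
  expect_equal(fit$per_trial$rr, rep(0.132, nrow(sim$trials)),
               tolerance = 1e-9)
})

test_that("noisy-data rate estimates converge near the generating rate", {
  # The log transform of additively noisy deficits has a small convexity
  # bias, so the pooled estimate is expected close to, not exactly at, the
  # generating rate (see the methods vignette).
  rr_hat <- vapply(1:60, function(i) {
    p <- generator_params(n_participants = 6, seed = 5000 + i)
    sim <- simulate_study(p)
    fit_rr(sim$recovery, sim$trials)$rr
  }, numeric(1))
  expect_lt(abs(mean(rr_hat) - 0.132), 0.005)
})

test_that("strength prediction follows the exponential recovery curve", {
  expect_equal(predict_ms(0.132, 100, 58.8, 0), 58.8)
  expect_equal(predict_ms(0.132, 100, 58.8, 6), 81.33895, tolerance = 1e-6)
  expect_equal(predict_ms(0.5, 90, 90, c(0, 3, 10)), rep(90, 3))
  traj <- predict_ms(0.132, 100, 58.8, seq(0, 40, by = 0.5))
  expect_true(all(diff(traj) > 0))
  expect_true(all(traj <= 100))
  expect_error(predict_ms(0.132, 100, 58.8, -1), "non-negative")
  expect_error(predict_ms(0, 100, 58.8, 1), "positive")
})

test_that("time_to_fraction inverts the recovery curve exactly", {
  # the published-scale case: ~16 min to reach 95% MVC
  t95 <- time_to_fraction(0.132, 0.588, 0.95)
  expect_equal(t95, 15.977, tolerance = 1e-4)

  # mutual-inverse property over random valid configurations
  set.seed(33)
  for (i in 1:25) {
    rr <- runif(1, 0.02, 1.5)
    ms0f <- runif(1, 0.1, 0.9)
    targ <- runif(1, ms0f + 0.01, 0.99)
    t <- time_to_fraction(rr, ms0f, targ)
    mvc <- runif(1, 60, 140)
    expect_equal(predict_ms(rr, mvc, ms0f * mvc, t) / mvc, targ,
                 tolerance = 1e-9)
  }

  # limit: a target just above the start takes vanishing time
  expect_lt(time_to_fraction(0.132, 0.588, 0.588 + 1e-9), 1e-6)

  expect_error(time_to_fraction(0.132, 0.588, 0.5), "already")
  expect_equal(time_to_fraction(0.132, 0.588, 0.5, lenient = TRUE), 0)
  expect_error(time_to_fraction(0.132, 0.588, 1), "asymptote")
  expect_error(time_to_fraction(-0.1, 0.588, 0.95), "positive")
})
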