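# Shared fixtures and independent oracles.

# Four hand-written trials, one per condition combination.
make_four_trials <- function() {
  data.frame(
    participant_id = c("P01", "P01", "P02", "P02"),
    push_force_N = c(20, 40, 20, 40),
    tool = c("small", "large", "large", "small"),
    tool_weight_kg = c(1.5, 5.6, 5.6, 1.5),
    mvc_N = c(100, 100, 80, 120),
    met_min = c(8, 2.5, 7, 3),
    ms0_N = c(58, 60, 47, 70),
    cr10_0 = c(8, 7.5, 8.5, 7),
    stringsAsFactors = FALSE)
}

# Generator settings with every noise source switched off.
noise_free_params <- function(n = 6, seed = 1, ...) {
  generator_params(n_participants = n, met_noise_sd = 0, ms0_frac_sd = 0,
                   recovery_noise_sd = 0, cr10_noise_sd = 0, seed = seed, ...)
}

# Brute-force normal equation for a through-origin simple regression.
slope_origin_oracle <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + x[i] * y[i]
    den <- den + x[i]^2
  }
  num / den
}

# ICC(2,1) absolute agreement from first-principles sums of squares,
# independent of the anova/lm path used by the package.
icc21_oracle <- function(x, y) {
  n <- length(x); k <- 2
  tab <- cbind(x, y)
  grand <- mean(tab)
  row_m <- rowMeans(tab)
  col_m <- colMeans(tab)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Random valid trials table for property-style round-trip tests.
random_trials <- function(n, seed) {
  set.seed(seed)
  mvc <- runif(n, 60, 150)
  force <- runif(n, 5, 0.9 * mvc)
  data.frame(
    participant_id = sprintf("R%03d", seq_len(n)),
    push_force_N = force,
    tool = sample(c("small", "large"), n, replace = TRUE),
    tool_weight_kg = runif(n, 1, 8),
    mvc_N = mvc,
    met_min = exp(rnorm(n, 1, 0.6)),
    ms0_N = mvc * runif(n, 0.3, 0.9),
    cr10_0 = runif(n, 0, 10),
    stringsAsFactors = FALSE)
}
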