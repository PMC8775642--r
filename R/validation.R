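#' Absolute and relative deviation of predictions
#'
#' For each prediction/measurement pair, the absolute deviation
#' `AD = |predicted - measured|` (in the measurement's units) and the relative
#' deviation `RD = AD / measured * 100` (percent). Means and sample (n-1)
#' standard deviations are reported.
#'
#' @param predicted,measured Equal-length numeric vectors; all measurements
#'   must be positive (RD is undefined at zero).
#' @return A list with `ad_mean`, `ad_sd`, `rd_mean`, `rd_sd` (percent) and
#'   `n`. SDs are `NA` for a single pair.
#' @examples
#' deviation_summary(predicted = 5, measured = 4)   # AD 1, RD 25%
#' @export
deviation_summary <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("predicted and measured must have the same length", call. = FALSE)
  if (length(measured) < 1) stop("need at least one pair", call. = FALSE)
  if (any(measured <= 0))
    stop("relative deviation is undefined for non-positive measurements",
         call. = FALSE)
  ad <- abs(predicted - measured)
  rd <- ad / measured * 100
  list(ad_mean = mean(ad), ad_sd = stats::sd(ad),
       rd_mean = mean(rd), rd_sd = stats::sd(rd),
       n = length(ad))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] with the preconditions of an agreement
#' analysis: at least three pairs and non-zero variance on both sides.
#'
#' @param x,y Equal-length numeric vectors.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(x, y)
}

#' Intraclass correlation for absolute agreement, ICC(2,1)
#'
#' Treats the pairs as an n x 2 subject-by-method table and computes the
#' two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with `k = 2` methods.
#' Unlike Pearson's r, a constant offset between methods lowers the ICC.
#'
#' @param x,y Equal-length numeric vectors (length >= 3), e.g. measured and
#'   predicted values.
#' @return The ICC. When every value in the table is identical there is no
#'   variance to disagree about; by convention 1 is returned with a
#'   `degenerate` attribute set.
#' @examples
#' icc_agreement(1:5, 1:5)                 # 1
#' icc_agreement(1:5, 1:5 + 10) < 0.5      # bias is penalised
#' @export
icc_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  vals <- c(x, y)
  if (max(vals) - min(vals) == 0) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  d <- data.frame(value = vals,
                  subject = factor(rep(seq_len(n), 2)),
                  method = factor(rep(1:2, each = n)))
  # only the mean squares are needed; F-test warnings on perfect fits
  # (identical methods) are irrelevant here
  ms <- suppressWarnings(
    stats::anova(stats::lm(value ~ subject + method, data = d)))
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["method", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = measured - predicted` are plotted (conceptually) against
#' pair averages; the bias is `mean(d)` and the limits of agreement are
#' `bias +/- k_sd * sd(d)`. The default multiplier is 2 rather than 1.96.
#'
#' @param measured,predicted Equal-length numeric vectors (length >= 2).
#' @param k_sd Limits-of-agreement multiplier (2 by default; 1.96 available).
#' @return A list with `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `outside_loa` (count of differences outside the limits), `n`, and a
#'   `points` data frame of (average, difference) pairs.
#' @examples
#' bland_altman(c(10, 12, 9), c(11, 11, 9))
#' @export
bland_altman <- function(measured, predicted, k_sd = 2) {
  if (length(measured) != length(predicted))
    stop("length mismatch", call. = FALSE)
  if (length(measured) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- measured - predicted
  a <- (measured + predicted) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- bias + c(-1, 1) * k_sd * sdd
  list(bias = bias, sd_diff = sdd, loa_low = loa[1], loa_high = loa[2],
       outside_loa = sum(d < loa[1] | d > loa[2]), n = length(d),
       points = data.frame(average = a, difference = d))
}

#' Validate an endurance model on hold-out trials
#'
#' Predicts the endurance time of every hold-out trial from its relative
#' load and assembles the full validation report: absolute/relative
#' deviation summary, Pearson r, ICC(2,1) and Bland-Altman agreement, plus
#' the per-trial prediction table.
#'
#' @param model A `met_fit` object, or any function mapping `f_MVC` to
#'   minutes (e.g. a registered external model, see
#'   [register_met_model()]).
#' @param trials Hold-out trials table.
#' @param group_label Optional label recorded in the report.
#' @param k_sd Bland-Altman limits multiplier.
#' @return An object of class `validation_report` with fields `deviation`,
#'   `pearson_r`, `icc`, `bland_altman`, `table`, `group_label`, `what`.
#' @export
validate_met_model <- function(model, trials, group_label = NULL, k_sd = 2) {
  trials <- validate_trials(trials)
  if (nrow(trials) == 0) stop("empty hold-out set", call. = FALSE)
  fmvc <- compute_fmvc(trials$push_force_N, trials$mvc_N)
  predicted <- if (inherits(model, "met_fit")) predict_met(model, fmvc)
               else if (is.function(model)) model(fmvc)
               else stop("model must be a met_fit or a function",
                         call. = FALSE)
  tab <- data.frame(participant_id = trials$participant_id,
                    push_force_N = trials$push_force_N, tool = trials$tool,
                    fmvc = fmvc, measured = trials$met_min,
                    predicted = predicted, stringsAsFactors = FALSE)
  .assemble_report(tab, group_label, what = "MET (min)", k_sd = k_sd)
}

#' Validate a recovery model on hold-out recovery series
#'
#' Predicts strength at every observed rest time of the hold-out trials from
#' each trial's own MVC and 0-min strength using the supplied recovery rate,
#' and assembles the same deviation/correlation/agreement report as
#' [validate_met_model()]. The 0-min rows are included (their prediction is
#' exact by construction).
#'
#' @param rr A fitted recovery rate (per minute) or a `recovery_fit`.
#' @param recovery Hold-out long-format recovery table.
#' @param trials The matching trials table.
#' @inheritParams validate_met_model
#' @return A `validation_report`.
#' @export
validate_recovery_model <- function(rr, recovery, trials,
                                    group_label = NULL, k_sd = 2) {
  if (inherits(rr, "recovery_fit")) rr <- rr$rr
  trials <- validate_trials(trials)
  recovery <- validate_recovery(recovery, trials = trials)
  if (nrow(recovery) == 0) stop("empty hold-out set", call. = FALSE)
  m <- match(trial_key(recovery), trial_key(trials))
  predicted <- predict_ms(rr, trials$mvc_N[m], trials$ms0_N[m],
                          recovery$t_min)
  tab <- data.frame(participant_id = recovery$participant_id,
                    push_force_N = recovery$push_force_N,
                    tool = recovery$tool, t_min = recovery$t_min,
                    measured = recovery$ms_N, predicted = predicted,
                    stringsAsFactors = FALSE)
  .assemble_report(tab, group_label, what = "MS (N)", k_sd = k_sd)
}

.assemble_report <- function(tab, group_label, what, k_sd) {
  out <- list(deviation = deviation_summary(tab$predicted, tab$measured),
              pearson_r = pearson_r(tab$measured, tab$predicted),
              icc = as.numeric(icc_agreement(tab$measured, tab$predicted)),
              bland_altman = bland_altman(tab$measured, tab$predicted,
                                          k_sd = k_sd),
              table = tab, group_label = group_label, what = what)
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation of predicted vs measured ", x$what,
      if (!is.null(x$group_label)) paste0(" [group ", x$group_label, "]"),
      "  (n = ", x$deviation$n, ")\n", sep = "")
  cat(sprintf("  AD %.3f (+/-%.3f)   RD %.2f (+/-%.2f)%%\n",
              x$deviation$ad_mean, x$deviation$ad_sd,
              x$deviation$rd_mean, x$deviation$rd_sd))
  cat(sprintf("  r = %.3f   ICC(2,1) = %.3f\n", x$pearson_r, x$icc))
  cat(sprintf("  Bland-Altman bias %.3f, LoA [%.3f, %.3f], outside: %d\n",
              x$bland_altman$bias, x$bland_altman$loa_low,
              x$bland_altman$loa_high, x$bland_altman$outside_loa))
  invisible(x)
}
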