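# Exponential strength-recovery model:
#   MS(t) = MS0 + (MVC - MS0) * (1 - exp(-RR * t))
# Linearised through the origin:  RR * t = ln((MVC - MS0) / (MVC - MS(t)))

#' Log-transform a recovery series for rate estimation
#'
#' Maps each post-rest strength observation to
#' `y = ln((MVC - MS0) / (MVC - MS_t))`, which under the exponential recovery
#' model equals `RR * t`. The 0-min observation is omitted (its transform is
#' identically zero and carries no information for a through-origin fit) and
#' observations at or above MVC — possible under measurement noise although
#' the model excludes them — are dropped and counted rather than treated as
#' errors.
#'
#' @param t_min Rest times in minutes.
#' @param ms_N Measured strengths in newtons, same length.
#' @param mvc_N,ms0_N Baseline strength (MVC) and 0-min strength for the
#'   trial; `ms0_N < mvc_N` is required.
#' @return Data frame with columns `t` and `y`; attribute `excluded` counts
#'   the dropped at-or-above-MVC points.
#' @examples
#' transform_recovery(0:3, c(58.8, 66.2, 70.1, 73.9), 100, 58.8)
#' @export
transform_recovery <- function(t_min, ms_N, mvc_N, ms0_N) {
  stopifnot(length(t_min) == length(ms_N), mvc_N > 0, ms0_N > 0)
  if (ms0_N >= mvc_N)
    stop("degenerate trial: 0-min strength at or above MVC leaves no ",
         "deficit to recover", call. = FALSE)
  keep <- t_min > 0
  t <- t_min[keep]; ms <- ms_N[keep]
  at_cap <- ms >= mvc_N
  excluded <- sum(at_cap)
  t <- t[!at_cap]; ms <- ms[!at_cap]
  if (length(t) == 0)
    stop("no usable observations after excluding t = 0 and at-MVC points",
         call. = FALSE)
  out <- data.frame(t = t, y = log((mvc_N - ms0_N) / (mvc_N - ms)))
  attr(out, "excluded") <- excluded
  out
}

#' Estimate the recovery rate by regression through the origin
#'
#' Pools the transformed `(t, y)` points of one or more trials and fits
#' `y = RR * t` without an intercept, so `RR = sum(t*y) / sum(t^2)`; the
#' reported R-squared is the uncentered `1 - SSR / sum(y^2)`. Pooling across
#' trials yields a single group-level rate; `mode = "per_trial"` additionally
#' returns one rate per trial for diagnostics.
#'
#' @param recovery A validated long-format recovery table.
#' @param trials The matching trials table supplying each trial's MVC and
#'   0-min strength.
#' @param mode `"pooled"` (one rate, the default) or `"per_trial"`.
#' @return An object of class `recovery_fit` with fields `rr` (positive,
#'   per minute), `r_squared`, `n_points`, `excluded_points`, and — in
#'   per-trial mode — a `per_trial` data frame.
#' @seealso [predict_ms()], [time_to_fraction()]
#' @export
fit_rr <- function(recovery, trials, mode = c("pooled", "per_trial")) {
  mode <- match.arg(mode)
  trials <- validate_trials(trials)
  recovery <- validate_recovery(recovery, trials = trials)
  tk <- trial_key(trials)
  pts <- vector("list", nrow(trials))
  excluded <- 0L
  for (i in seq_len(nrow(trials))) {
    s <- recovery[trial_key(recovery) == tk[i], , drop = FALSE]
    if (nrow(s) == 0) next
    tp <- transform_recovery(s$t_min, s$ms_N, trials$mvc_N[i],
                             trials$ms0_N[i])
    excluded <- excluded + attr(tp, "excluded")
    tp$key <- tk[i]
    pts[[i]] <- tp
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) == 0)
    stop("no transformed points to fit", call. = FALSE)
  pooled <- fit_rr_points(pts$t, pts$y)
  out <- list(rr = pooled$slope, r_squared = pooled$r_squared,
              n_points = nrow(pts), excluded_points = excluded)
  if (mode == "per_trial") {
    per <- lapply(split(pts, pts$key), function(s) {
      f <- fit_rr_points(s$t, s$y)
      data.frame(key = s$key[1], rr = f$slope, r_squared = f$r_squared,
                 n_points = nrow(s), stringsAsFactors = FALSE)
    })
    out$per_trial <- do.call(rbind, c(per, make.row.names = FALSE))
  }
  if (out$rr <= 0)
    warning("fitted recovery rate is not positive; the strength data do ",
            "not show net recovery", call. = FALSE)
  class(out) <- "recovery_fit"
  out
}

# Through-origin slope and uncentered R-squared for a point set.
fit_rr_points <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 1)
  slope <- sum(t * y) / sum(t^2)
  ssr <- sum((y - slope * t)^2)
  tot <- sum(y^2)
  r2 <- if (tot == 0) 1 else 1 - ssr / tot
  list(slope = slope, r_squared = min(max(r2, 0), 1))
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat("Exponential recovery fit (through-origin, pooled)\n",
      "  RR = ", format(x$rr, digits = 4), " per min",
      "   R-squared = ", format(x$r_squared, digits = 4),
      "   points = ", x$n_points,
      if (x$excluded_points > 0)
        paste0("   excluded at/above MVC = ", x$excluded_points),
      "\n", sep = "")
  invisible(x)
}

#' Predict strength after a rest period
#'
#' Evaluates `MS(t) = MS0 + (MVC - MS0) * (1 - exp(-rr * t))`: strength rises
#' from the 0-min value `MS0` toward the MVC asymptote at rate `rr`.
#'
#' @param rr Recovery rate per minute, positive.
#' @param mvc_N,ms0_N Baseline strength and 0-min strength in newtons,
#'   `0 < ms0_N <= mvc_N`.
#' @param t_min Rest time(s) in minutes, non-negative.
#' @return Predicted strength(s) in newtons.
#' @examples
#' predict_ms(0.132, 100, 58.8, 0:6)
#' @export
predict_ms <- function(rr, mvc_N, ms0_N, t_min) {
  if (rr <= 0) stop("recovery rate must be positive", call. = FALSE)
  if (any(t_min < 0)) stop("rest time must be non-negative", call. = FALSE)
  stopifnot(ms0_N > 0, ms0_N <= mvc_N)
  ms0_N + (mvc_N - ms0_N) * (1 - exp(-rr * t_min))
}

#' Rest time needed to reach a target strength fraction
#'
#' Closed-form inversion of the recovery model on the MVC-fraction scale:
#' `t = -(1/rr) * ln(1 - (target - ms0_frac) / (1 - ms0_frac))`. The target
#' must lie strictly below 1 because full MVC is the asymptote and is never
#' reached in finite time.
#'
#' @param rr Recovery rate per minute, positive.
#' @param ms0_frac 0-min strength as a fraction of MVC, in `(0, 1)`.
#' @param target_frac Target strength fraction, in `(ms0_frac, 1)`.
#' @param lenient If `TRUE`, a target at or below the starting fraction
#'   returns 0 instead of raising an error.
#' @return Rest time in minutes.
#' @examples
#' time_to_fraction(0.132, 0.588, 0.95)   # about 16 minutes
#' @export
time_to_fraction <- function(rr, ms0_frac, target_frac, lenient = FALSE) {
  if (rr <= 0) stop("recovery rate must be positive", call. = FALSE)
  if (ms0_frac <= 0 || ms0_frac >= 1)
    stop("ms0_frac must lie in (0, 1)", call. = FALSE)
  if (target_frac >= 1)
    stop("target fraction >= 1 is never reached: MVC is the asymptote",
         call. = FALSE)
  if (target_frac <= ms0_frac) {
    if (lenient) return(0)
    stop("target fraction at or below the starting fraction: already ",
         "recovered", call. = FALSE)
  }
  -log(1 - (target_frac - ms0_frac) / (1 - ms0_frac)) / rr
}
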