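#' Relative load as a fraction of MVC
#'
#' `f_MVC = load / MVC`, the dimensionless relative load driving endurance.
#' A load above MVC is infeasible for a sustained exertion and is rejected.
#'
#' @param load_N,mvc_N Positive forces in newtons (vectorised).
#' @return Numeric vector of fractions in `(0, 1]`.
#' @examples
#' compute_fmvc(20, 100)
#' @export
compute_fmvc <- function(load_N, mvc_N) {
  if (any(load_N <= 0) || any(mvc_N <= 0))
    stop("load and MVC must be positive", call. = FALSE)
  if (any(load_N > mvc_N))
    stop("load exceeds MVC: sustained endurance is undefined above MVC",
         call. = FALSE)
  load_N / mvc_N
}

#' Fit a maximum-endurance-time model by log-linearised least squares
#'
#' Two candidate forms relate endurance time to relative load:
#' exponential, `MET = k * exp(c * f_MVC)`, and power, `MET = k * f_MVC^c`.
#' Taking natural logarithms gives a linear model of `ln(MET)` on `f_MVC`
#' (exponential) or `ln(f_MVC)` (power), fitted by ordinary least squares.
#' Without an intercept the line is forced through the origin (so `k = 1`)
#' and the reported R-squared is the uncentered version
#' `1 - SSR / sum(y^2)`; with an intercept `k = exp(intercept)` and the usual
#' centered R-squared is reported.
#'
#' @param trials A validated trials table, or a data frame with at least
#'   `push_force_N`, `mvc_N` and `met_min` columns.
#' @param form `"power"` or `"exponential"`.
#' @param with_intercept Fit an intercept? Default `FALSE` (through the
#'   origin).
#' @return An object of class `met_fit` with fields `form`,
#'   `with_intercept`, `k`, `c`, `r_squared`, `n` and `residual_log_sd`.
#' @seealso [predict_met()], [select_best()], [fit_met_candidates()]
#' @examples
#' tr <- simulate_study(generator_params(n_participants = 6, seed = 2))$trials
#' fit_met(tr, form = "power")
#' @export
fit_met <- function(trials, form = c("power", "exponential"),
                    with_intercept = FALSE) {
  form <- match.arg(form)
  stopifnot(all(c("push_force_N", "mvc_N", "met_min") %in% names(trials)))
  if (any(trials$met_min <= 0))
    stop("all MET values must be positive", call. = FALSE)
  fmvc <- compute_fmvc(trials$push_force_N, trials$mvc_N)
  y <- log(trials$met_min)
  x <- if (form == "power") log(fmvc) else fmvc
  n <- length(y)
  need <- if (with_intercept) 3L else 2L
  if (n < need)
    stop("need at least ", need, " trials for this fit, got ", n,
         call. = FALSE)
  if (max(x) - min(x) < 1e-12)
    stop("relative load is constant across trials: singular fit",
         call. = FALSE)
  fit <- if (with_intercept) stats::lm(y ~ x) else stats::lm(y ~ 0 + x)
  res <- stats::residuals(fit)
  ssr <- sum(res^2)
  tot <- if (with_intercept) sum((y - mean(y))^2) else sum(y^2)
  # a response with zero total variation and zero residuals is a perfect fit
  r2 <- if (tot == 0) as.numeric(ssr <= 1e-12) else 1 - ssr / tot
  cf <- stats::coef(fit)
  out <- list(form = form,
              with_intercept = with_intercept,
              k = if (with_intercept) exp(unname(cf[1])) else 1,
              c = unname(cf[length(cf)]),
              r_squared = min(max(r2, 0), 1),
              n = n,
              residual_log_sd = sqrt(ssr / stats::df.residual(fit)))
  class(out) <- "met_fit"
  out
}

#' Fit all four candidate MET models
#'
#' Exponential and power forms, each with and without an intercept — the
#' candidate set from which the endurance model is selected by R-squared.
#'
#' @inheritParams fit_met
#' @return A list of four `met_fit` objects named
#'   `exponential_intercept`, `exponential_origin`, `power_intercept`,
#'   `power_origin`.
#' @export
fit_met_candidates <- function(trials) {
  grid <- expand.grid(form = c("exponential", "power"),
                      with_intercept = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(grid)), function(i)
    fit_met(trials, grid$form[i], grid$with_intercept[i]))
  names(fits) <- paste0(grid$form,
                        ifelse(grid$with_intercept, "_intercept", "_origin"))
  fits
}

#' Select the best-fitting MET model
#'
#' Picks the candidate with the highest R-squared. Exact ties are broken in
#' favour of the through-origin fit over the intercept fit, then the power
#' form over the exponential.
#'
#' @param fits A non-empty list of `met_fit` objects.
#' @return The selected `met_fit`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0) stop("empty list of fits", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "met_fit")))
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  icpt <- vapply(fits, `[[`, logical(1), "with_intercept")
  pow <- vapply(fits, `[[`, character(1), "form") == "power"
  ord <- order(-r2, icpt, !pow)
  fits[[ord[1]]]
}

#' Predict endurance time from relative load
#'
#' Evaluates a fitted MET model: `k * f_MVC^c` (power) or
#' `k * exp(c * f_MVC)` (exponential). With a negative exponent the
#' prediction is strictly decreasing in relative load.
#'
#' @param fit A `met_fit` object.
#' @param fmvc Relative load(s) in `(0, 1]`.
#' @return Predicted endurance time(s) in minutes, strictly positive.
#' @examples
#' fit <- list(form = "power", with_intercept = FALSE, k = 1, c = -1.15)
#' class(fit) <- "met_fit"
#' predict_met(fit, c(0.2, 0.5, 1))
#' @export
predict_met <- function(fit, fmvc) {
  stopifnot(inherits(fit, "met_fit"))
  if (any(fmvc <= 0) || any(fmvc > 1))
    stop("relative load must lie in (0, 1]", call. = FALSE)
  if (fit$form == "power") fit$k * fmvc^fit$c
  else fit$k * exp(fit$c * fmvc)
}

#' @export
predict.met_fit <- function(object, fmvc, ...) predict_met(object, fmvc)

#' @export
print.met_fit <- function(x, ...) {
  eq <- if (x$form == "power") {
    if (x$with_intercept) sprintf("MET = %.4g * f_MVC^%.4g", x$k, x$c)
    else sprintf("MET = f_MVC^%.4g", x$c)
  } else {
    if (x$with_intercept) sprintf("MET = %.4g * exp(%.4g * f_MVC)", x$k, x$c)
    else sprintf("MET = exp(%.4g * f_MVC)", x$c)
  }
  cat("MET model (", x$form,
      if (x$with_intercept) ", with intercept" else ", through origin",
      ")\n  ", eq, "\n  R-squared: ", format(x$r_squared, digits = 4),
      "  n = ", x$n, "\n", sep = "")
  invisible(x)
}

# --- plugin registry for externally published MET models ------------------

.met_registry <- new.env(parent = emptyenv())

#' Register or retrieve an external MET model
#'
#' Endurance models from the literature are usually published as a formula in
#' the relative load. Any function mapping `f_MVC` to minutes can be
#' registered under a name and then validated against data with
#' [validate_met_model()] exactly like a fitted model. No coefficients are
#' shipped; the user supplies the mapping.
#'
#' @param name Model name.
#' @param fun Function of one argument (`f_MVC` in `(0, 1]`) returning
#'   minutes.
#' @return `register_met_model()` returns `fun` invisibly;
#'   `external_met_model()` returns the registered function;
#'   `list_met_models()` the registered names.
#' @examples
#' register_met_model("toy_power", function(f) f^-1.2)
#' external_met_model("toy_power")(0.5)
#' @export
register_met_model <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1, is.function(fun))
  assign(name, fun, envir = .met_registry)
  invisible(fun)
}

#' @rdname register_met_model
#' @export
external_met_model <- function(name) {
  if (!exists(name, envir = .met_registry, inherits = FALSE))
    stop("no MET model registered under '", name, "'", call. = FALSE)
  get(name, envir = .met_registry, inherits = FALSE)
}

#' @rdname register_met_model
#' @export
list_met_models <- function() ls(.met_registry)
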