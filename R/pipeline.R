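#' Configure an end-to-end fatigue/recovery analysis
#'
#' Either a pair of input CSV paths (trials + recovery) or a set of generator
#' parameters must be supplied, not both. The analysis splits trials into
#' groups A and B, fits the candidate endurance models and the pooled
#' recovery rate on group A, validates both on group B, and extrapolates the
#' rest time needed to reach the target strength fraction.
#'
#' @param trials_path,recovery_path Input CSV paths (see [read_trials()]).
#' @param params A [generator_params()] object; used when no input paths are
#'   given.
#' @param ab_map A/B membership map, see [split_ab()].
#' @param recovery_mode `"pooled"` or `"per_trial"`, see [fit_rr()].
#' @param target_fraction Target strength fraction for the recovery-time
#'   extrapolation, in (0, 1); default 0.95.
#' @param ms0_fraction `"data"` to use the mean 0-min strength fraction of
#'   the analysed trials, or a number in (0, 1) to use a fixed fraction.
#' @param out_dir Optional directory for the JSON report bundle.
#' @param seed Seed recorded in the run log and used when simulating.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(trials_path = NULL, recovery_path = NULL,
                            params = NULL,
                            ab_map = default_ab_map(),
                            recovery_mode = c("pooled", "per_trial"),
                            target_fraction = 0.95,
                            ms0_fraction = "data",
                            out_dir = NULL, seed = 1L) {
  has_paths <- !is.null(trials_path) || !is.null(recovery_path)
  if (has_paths && (is.null(trials_path) || is.null(recovery_path)))
    stop("supply both trials_path and recovery_path", call. = FALSE)
  if (has_paths && !is.null(params))
    stop("supply either input paths or generator params, not both",
         call. = FALSE)
  if (!has_paths && is.null(params))
    params <- generator_params(seed = seed)
  if (target_fraction <= 0 || target_fraction >= 1)
    stop("target_fraction must lie in (0, 1)", call. = FALSE)
  if (is.numeric(ms0_fraction) &&
      (ms0_fraction <= 0 || ms0_fraction >= 1))
    stop("a numeric ms0_fraction must lie in (0, 1)", call. = FALSE)
  cfg <- list(trials_path = trials_path, recovery_path = recovery_path,
              params = params, ab_map = ab_map,
              recovery_mode = match.arg(recovery_mode),
              target_fraction = target_fraction,
              ms0_fraction = ms0_fraction,
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "analysis_config"
  cfg
}

#' Read an analysis configuration from JSON or YAML
#'
#' Recognised keys mirror the arguments of [analysis_config()]; generator
#' parameters are given under a `params` key.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return An `analysis_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed to read YAML configs",
           call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$ab_map)) raw$ab_map <- as.data.frame(raw$ab_map)
  if (!is.null(raw$params)) raw$params <- do.call(generator_params, raw$params)
  do.call(analysis_config, raw)
}

#' Run the full fit-and-validate analysis
#'
#' Loads or simulates the study data, splits the trials into groups A and B,
#' fits the four candidate endurance models on group A and selects the best
#' by R-squared, fits the pooled recovery rate on group A's recovery series,
#' validates both selected models on group B, extrapolates the rest time to
#' the target strength fraction, and summarises endurance by condition. With
#' `out_dir` set, writes `met_fit.json`, `recovery_fit.json`,
#' `validation.json`, `recovery_time.json` and `run_log.json`; re-running
#' with the same seed reproduces the bundle byte for byte.
#'
#' @param config An [analysis_config()] object.
#' @return A list with `trials`, `recovery`, `groups`, `met_fits` (all four
#'   candidates), `met_selected`, `recovery_fit`, `met_validation`,
#'   `recovery_validation`, `recovery_time`, `condition_summary`.
#' @examples
#' cfg <- analysis_config(params = generator_params(n_participants = 6,
#'                                                  seed = 11))
#' res <- run_full_analysis(cfg)
#' res$met_selected
#' @export
run_full_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (!is.null(config$trials_path)) {
    trials <- read_trials(config$trials_path)
    recovery <- read_recovery(config$recovery_path, trials_check = trials)
  } else {
    sim <- simulate_study(config$params)
    trials <- sim$trials
    recovery <- sim$recovery
  }
  groups <- split_ab(trials, map = config$ab_map)
  rec_groups <- lapply(groups, function(g)
    recovery[trial_key(recovery) %in% trial_key(g), , drop = FALSE])

  met_fits <- fit_met_candidates(groups$A)
  met_sel <- select_best(met_fits)
  rec_fit <- fit_rr(rec_groups$A, groups$A, mode = config$recovery_mode)

  met_val <- validate_met_model(met_sel, groups$B, group_label = "B")
  rec_val <- validate_recovery_model(rec_fit, rec_groups$B, groups$B,
                                     group_label = "B")

  ms0_frac <- if (identical(config$ms0_fraction, "data"))
    mean(trials$ms0_N / trials$mvc_N) else config$ms0_fraction
  rec_time <- list(rr = rec_fit$rr, ms0_fraction = ms0_frac,
                   target_fraction = config$target_fraction,
                   minutes = time_to_fraction(rec_fit$rr, ms0_frac,
                                              config$target_fraction))

  res <- list(trials = trials, recovery = recovery, groups = groups,
              met_fits = met_fits, met_selected = met_sel,
              recovery_fit = rec_fit,
              met_validation = met_val, recovery_validation = rec_val,
              recovery_time = rec_time,
              condition_summary = summarize_conditions(trials))

  if (!is.null(config$out_dir)) .write_bundle(res, config)
  res
}

.write_bundle <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, file)
    jsonlite::write_json(x, file.path(config$out_dir, file),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  strip <- function(f) { f <- unclass(f); f$table <- NULL; f$points <- NULL; f }
  wj(list(candidates = lapply(res$met_fits, unclass),
          selected = unclass(res$met_selected)), "met_fit.json")
  wj(strip(unclass(res$recovery_fit)), "recovery_fit.json")
  wj(list(met = strip_report(res$met_validation),
          recovery = strip_report(res$recovery_validation)),
     "validation.json")
  wj(res$recovery_time, "recovery_time.json")
  wj(list(seed = config$seed,
          n_trials = nrow(res$trials),
          n_recovery_rows = nrow(res$recovery),
          n_group_a = nrow(res$groups$A), n_group_b = nrow(res$groups$B),
          excluded_recovery_points = res$recovery_fit$excluded_points,
          package_version = as.character(utils::packageVersion("fatiguekit")),
          source = if (is.null(config$trials_path)) "simulated" else "csv"),
     "run_log.json")
  invisible(config$out_dir)
}

strip_report <- function(r) {
  r <- unclass(r)
  r$table <- NULL
  r$bland_altman$points <- NULL
  r
}

#' Summarise endurance time by experimental condition
#'
#' Per (push force, tool) cell: number of trials, mean and sample SD of the
#' endurance time; plus one pooled row per force level (tool `"all"`). The SD
#' of a single-trial cell is `NA`.
#'
#' @param trials A validated trials table.
#' @return Data frame with columns `push_force_N`, `tool`, `n`,
#'   `met_mean_min`, `met_sd_min`.
#' @export
summarize_conditions <- function(trials) {
  trials <- validate_trials(trials)
  if (nrow(trials) == 0) stop("no trials to summarise", call. = FALSE)
  cell <- function(df, tool_label) {
    data.frame(push_force_N = df$push_force_N[1], tool = tool_label,
               n = nrow(df), met_mean_min = mean(df$met_min),
               met_sd_min = if (nrow(df) > 1) stats::sd(df$met_min)
                            else NA_real_,
               stringsAsFactors = FALSE)
  }
  per <- lapply(split(trials, list(trials$push_force_N, trials$tool),
                      drop = TRUE),
                function(df) cell(df, df$tool[1]))
  pooled <- lapply(split(trials, trials$push_force_N),
                   function(df) cell(df, "all"))
  out <- do.call(rbind, c(per, pooled, make.row.names = FALSE))
  out <- out[order(out$push_force_N, out$tool == "all", out$tool), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
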