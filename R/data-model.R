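#' @keywords internal
"_PACKAGE"

# Column schemas for the two CSV formats. Strengths and forces are newtons,
# times are minutes; there is no unit-conversion layer.
.trials_cols <- c("participant_id", "push_force_N", "tool", "tool_weight_kg",
                  "mvc_N", "met_min", "ms0_N", "cr10_0")
.recovery_cols <- c("participant_id", "push_force_N", "tool", "t_min",
                    "ms_N", "cr10")

#' Default experimental conditions
#'
#' The four push-force by hammer combinations of the demolition-task design:
#' push force 20 or 40 N crossed with a small (1.5 kg) or large (5.6 kg)
#' demolition hammer.
#'
#' @param push_forces Numeric vector of push-force levels in newtons.
#' @param tool_weights Named numeric vector of tool weights in kg; names are
#'   the tool labels.
#' @return A data frame with columns `push_force_N`, `tool`, `tool_weight_kg`,
#'   one row per condition.
#' @examples
#' default_conditions()
#' @export
default_conditions <- function(push_forces = c(20, 40),
                               tool_weights = c(small = 1.5, large = 5.6)) {
  stopifnot(all(push_forces > 0), all(tool_weights > 0),
            !is.null(names(tool_weights)))
  out <- expand.grid(push_force_N = push_forces, tool = names(tool_weights),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$tool_weight_kg <- unname(tool_weights[out$tool])
  out[order(out$push_force_N, out$tool), , drop = FALSE]
}

#' Validate a table of fatigue trials
#'
#' Checks the invariants of one exhaustive-push record: positive MVC and
#' endurance time, post-exertion strength no larger than MVC, push force no
#' larger than MVC (relative load at most 1), and a CR-10 rating in `[0, 10]`.
#'
#' @param trials Data frame with columns
#'   `participant_id, push_force_N, tool, tool_weight_kg, mvc_N, met_min,
#'   ms0_N, cr10_0`.
#' @return The validated data frame, invisibly reordered columns first.
#' @export
validate_trials <- function(trials) {
  trials <- .check_columns(trials, .trials_cols, "trials")
  num <- setdiff(.trials_cols, c("participant_id", "tool"))
  for (col in num) {
    if (!is.numeric(trials[[col]]))
      stop("column '", col, "' must be numeric", call. = FALSE)
    if (anyNA(trials[[col]]))
      stop("column '", col, "' contains missing values", call. = FALSE)
  }
  .row_check(trials$mvc_N > 0, trials, "mvc_N must be > 0")
  .row_check(trials$met_min > 0, trials, "met_min must be > 0")
  .row_check(trials$ms0_N > 0, trials, "ms0_N must be > 0")
  .row_check(trials$ms0_N <= trials$mvc_N, trials,
             "ms0_N exceeds mvc_N (post-exertion strength above MVC)")
  .row_check(trials$push_force_N > 0, trials, "push_force_N must be > 0")
  .row_check(trials$push_force_N <= trials$mvc_N, trials,
             "push_force_N exceeds mvc_N (relative load above 1)")
  .row_check(trials$cr10_0 >= 0 & trials$cr10_0 <= 10, trials,
             "cr10_0 outside [0, 10]")
  trials[, union(.trials_cols, names(trials)), drop = FALSE]
}

#' Validate a long-format recovery table
#'
#' One row per trial per minute of rest: the same trial key as the trials
#' table plus rest time `t_min`, measured strength `ms_N` and the CR-10
#' rating. Each trial's series must start at `t = 0`, have strictly
#' increasing times, positive strengths, and ratings in `[0, 10]`. When the
#' matching trials table is supplied, the 0-min strength is checked against
#' the trial's recorded post-exertion strength to within `tol` newtons.
#'
#' @param recovery Data frame with columns
#'   `participant_id, push_force_N, tool, t_min, ms_N, cr10`.
#' @param trials Optional trials table for the 0-min consistency check.
#' @param tol Tolerance in newtons for the 0-min consistency check.
#' @return The validated data frame, sorted by trial key and time.
#' @export
validate_recovery <- function(recovery, trials = NULL, tol = 1e-6) {
  recovery <- .check_columns(recovery, .recovery_cols, "recovery")
  for (col in c("push_force_N", "t_min", "ms_N", "cr10")) {
    if (!is.numeric(recovery[[col]]))
      stop("column '", col, "' must be numeric", call. = FALSE)
    if (anyNA(recovery[[col]]))
      stop("column '", col, "' contains missing values", call. = FALSE)
  }
  .row_check(recovery$ms_N > 0, recovery, "ms_N must be > 0")
  .row_check(recovery$cr10 >= 0 & recovery$cr10 <= 10, recovery,
             "cr10 outside [0, 10]")
  .row_check(recovery$t_min >= 0, recovery, "t_min must be >= 0")
  key <- trial_key(recovery)
  recovery <- recovery[order(key, recovery$t_min), , drop = FALSE]
  for (k in unique(key)) {
    s <- recovery[trial_key(recovery) == k, , drop = FALSE]
    if (s$t_min[1] != 0)
      stop("recovery series '", k, "' does not start at t = 0", call. = FALSE)
    if (any(diff(s$t_min) <= 0))
      stop("recovery series '", k, "' has non-increasing times", call. = FALSE)
  }
  if (!is.null(trials)) {
    trials <- validate_trials(trials)
    at0 <- recovery[recovery$t_min == 0, , drop = FALSE]
    m <- match(trial_key(at0), trial_key(trials))
    if (anyNA(m))
      stop("recovery series without a matching trial: ",
           paste(trial_key(at0)[is.na(m)], collapse = ", "), call. = FALSE)
    off <- abs(at0$ms_N - trials$ms0_N[m])
    if (any(off > tol))
      stop("0-min strength differs from the trial's ms0_N by more than ",
           tol, " N for: ",
           paste(trial_key(at0)[off > tol], collapse = ", "), call. = FALSE)
  }
  rownames(recovery) <- NULL
  recovery
}

#' Composite key identifying a trial
#'
#' Concatenates participant, push force and tool — the columns shared by the
#' trials and recovery tables — into one key per row, for joining or
#' subsetting recovery rows by trial.
#'
#' @param df A trials or recovery data frame.
#' @return Character vector of keys, one per row.
#' @examples
#' tr <- simulate_study(generator_params(n_participants = 2, seed = 1))
#' rec_a <- tr$recovery[trial_key(tr$recovery) %in%
#'                        trial_key(split_ab(tr$trials)$A), ]
#' @export
trial_key <- function(df) {
  paste(df$participant_id, df$push_force_N, df$tool, sep = "|")
}

.check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop(what, " must be a data frame", call. = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

.row_check <- function(ok, df, msg) {
  if (!all(ok))
    stop(msg, " (row ", paste(which(!ok), collapse = ", "), ")",
         call. = FALSE)
  invisible(TRUE)
}

#' Read and write trial and recovery CSV files
#'
#' Plain UTF-8 CSV with a fixed header; numeric values are written with 15
#' significant digits so a write/read cycle is lossless. `read_trials()` and
#' `read_recovery()` validate every row and report the offending row index on
#' failure.
#'
#' @param path File path.
#' @param trials,recovery Validated tables as produced by the generator or a
#'   previous read.
#' @return The validated data frame (readers); the path, invisibly (writers).
#' @seealso [validate_trials()], [validate_recovery()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(df)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  .write_csv(trials[, .trials_cols, drop = FALSE], path)
}

#' @rdname read_trials
#' @param trials_check Optional trials table passed to [validate_recovery()]
#'   for the 0-min consistency check.
#' @export
read_recovery <- function(path, trials_check = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_recovery(df, trials = trials_check)
}

#' @rdname read_trials
#' @export
write_recovery <- function(recovery, path) {
  recovery <- validate_recovery(recovery)
  .write_csv(recovery[, .recovery_cols, drop = FALSE], path)
}

.write_csv <- function(df, path) {
  for (col in names(df))
    if (is.numeric(df[[col]]))
      df[[col]] <- formatC(df[[col]], digits = 15, format = "g")
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Split trials into model-building and validation halves
#'
#' The diagonal split used for cross-validation of the endurance and recovery
#' models: group A holds (20 N, small hammer) and (40 N, large hammer) trials,
#' group B holds (20 N, large hammer) and (40 N, small hammer) trials, so each
#' group contains both force levels and both tools. The membership map is
#' configurable for other designs.
#'
#' @param trials A validated trials table.
#' @param map Data frame with columns `push_force_N`, `tool`, `group`
#'   (`"A"` or `"B"`) covering every condition present in `trials`.
#' @return A list with elements `A` and `B`, each a trials data frame.
#'   Together they partition the input.
#' @examples
#' tr <- simulate_study(generator_params(n_participants = 4, seed = 1))$trials
#' ab <- split_ab(tr)
#' nrow(ab$A) + nrow(ab$B) == nrow(tr)
#' @export
split_ab <- function(trials, map = default_ab_map()) {
  trials <- validate_trials(trials)
  stopifnot(all(c("push_force_N", "tool", "group") %in% names(map)),
            all(map$group %in% c("A", "B")))
  mk <- paste(map$push_force_N, map$tool, sep = "|")
  tk <- paste(trials$push_force_N, trials$tool, sep = "|")
  m <- match(tk, mk)
  if (anyNA(m))
    stop("condition(s) not covered by the A/B map: ",
         paste(unique(tk[is.na(m)]), collapse = ", "), call. = FALSE)
  g <- map$group[m]
  list(A = trials[g == "A", , drop = FALSE],
       B = trials[g == "B", , drop = FALSE])
}

#' @rdname split_ab
#' @export
default_ab_map <- function() {
  data.frame(push_force_N = c(20, 40, 20, 40),
             tool = c("small", "large", "large", "small"),
             group = c("A", "A", "B", "B"),
             stringsAsFactors = FALSE)
}

#' Relative-weight grouping of tool versus body mass
#'
#' Relative weight (RW) is the hand-tool weight as a percentage of the
#' operator's body mass. Operators are binned into light (L), normal (N) and
#' heavy (H) groups; the default bin edges are 1.9-4.7, 4.8-7.5 and 7.6-10.3
#' percent. Because the published bins are rounded there are 0.1-point gaps
#' between them; an RW falling in a gap (or outside the outer edges) is
#' assigned to the nearest bin and flagged rather than rejected.
#'
#' @param tool_weight_kg,body_mass_kg Positive masses in kg (vectorised,
#'   recycled to common length).
#' @param bins Data frame with columns `label`, `lo`, `hi` (percent).
#' @return Data frame with columns `rw` (percent), `label`, and `gap`
#'   (`TRUE` when the value fell outside every bin and was mapped to the
#'   nearest one).
#' @examples
#' assign_rw_group(c(5.6, 1.5), 68.17)
#' @export
assign_rw_group <- function(tool_weight_kg, body_mass_kg,
                            bins = default_rw_bins()) {
  if (any(tool_weight_kg <= 0) || any(body_mass_kg <= 0))
    stop("masses must be positive", call. = FALSE)
  stopifnot(all(c("label", "lo", "hi") %in% names(bins)),
            all(bins$lo < bins$hi))
  n <- max(length(tool_weight_kg), length(body_mass_kg))
  tw <- rep_len(tool_weight_kg, n)
  bm <- rep_len(body_mass_kg, n)
  rw <- 100 * tw / bm
  label <- character(n)
  gap <- logical(n)
  for (i in seq_len(n)) {
    inside <- rw[i] >= bins$lo & rw[i] <= bins$hi
    if (any(inside)) {
      label[i] <- bins$label[which(inside)[1]]
    } else {
      d <- pmin(abs(rw[i] - bins$lo), abs(rw[i] - bins$hi))
      label[i] <- bins$label[which.min(d)]
      gap[i] <- TRUE
    }
  }
  if (any(gap))
    warning(sum(gap), " RW value(s) fell outside the bins and were mapped ",
            "to the nearest bin", call. = FALSE)
  data.frame(rw = rw, label = label, gap = gap, stringsAsFactors = FALSE)
}

#' @rdname assign_rw_group
#' @export
default_rw_bins <- function() {
  data.frame(label = c("L", "N", "H"),
             lo = c(1.9, 4.8, 7.6),
             hi = c(4.7, 7.5, 10.3),
             stringsAsFactors = FALSE)
}
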