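#' Write and read trial logs
#'
#' Trial logs are comma-separated UTF-8 text with a header row, "."
#' decimal, one row per trial: `trial_index`, `object_id`, `category`,
#' `difficulty` (0 = Low/Easy, 1 = High/Hard), `handle_side`,
#' `touch_outcome` (1 = self touch, -1 = partner touch, 0 = none),
#' `correct`, `reaction_time` (seconds, at most 3). The reader validates
#' the vocabulary of every coded column and derives the action indicators
#' `a_s`, `a_p` from `touch_outcome`.
#'
#' @param trials A trial data.frame (e.g. from [simulate_session()]).
#' @param path File path.
#' @return `write_trial_log` returns `path` invisibly; `read_trial_log`
#'   returns a validated trial data.frame with `a_s`/`a_p` columns.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_index", "touch_outcome", "correct", "reaction_time",
                "difficulty")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0)
    stop("trial log is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!all(trials$touch_outcome %in% c(1, -1, 0)))
    stop("unknown touch_outcome code; allowed codes are 1, -1, 0",
         call. = FALSE)
  if (!all(trials$difficulty %in% c(0, 1)))
    stop("difficulty must be 0 (Low/Easy) or 1 (High/Hard)", call. = FALSE)
  if (!all(trials$correct %in% c(0, 1)))
    stop("correct must be 0 or 1", call. = FALSE)
  if (any(trials$reaction_time < 0 | trials$reaction_time > 3))
    stop("reaction_time must lie in [0, 3] seconds", call. = FALSE)
  acts <- actions_from_outcome(trials$touch_outcome)
  trials$a_s <- acts$a_s
  trials$a_p <- acts$a_p
  trials
}

#' Write and read gaze streams
#'
#' Gaze streams are stored as CSV (or JSON-lines when the path ends in
#' `.jsonl`) with columns `participant_id`, `trial_id`, `phase`, `t`,
#' `x`, `y`, `z`. On reading, rows with any missing coordinate are
#' dropped and counted (reported via the `"n_dropped"` attribute), and
#' timestamps are checked to be strictly increasing within each
#' participant x trial x phase series.
#'
#' @param gaze A gaze stream data.frame.
#' @param path File path (`.csv` or `.jsonl`).
#' @return `write_gaze_stream` returns `path` invisibly;
#'   `read_gaze_stream` returns the cleaned gaze data.frame.
#' @export
write_gaze_stream <- function(gaze, path) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    jsonlite::stream_out(gaze, con, verbose = FALSE, digits = NA)
  } else {
    utils::write.csv(gaze, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_gaze_stream
#' @export
read_gaze_stream <- function(path) {
  gaze <- if (grepl("\\.jsonl$", path)) {
    con <- file(path, "r")
    on.exit(close(con))
    jsonlite::stream_in(con, verbose = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(gaze) == 0) {
    warning("empty gaze stream: ", path, call. = FALSE)
    attr(gaze, "n_dropped") <- 0L
    return(gaze)
  }
  required <- c("participant_id", "trial_id", "phase", "t", "x", "y", "z")
  missing <- setdiff(required, names(gaze))
  if (length(missing) > 0)
    stop("gaze stream is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  complete <- stats::complete.cases(gaze[, c("t", "x", "y", "z")])
  n_dropped <- sum(!complete)
  gaze <- gaze[complete, , drop = FALSE]
  key <- interaction(gaze$participant_id, gaze$trial_id, gaze$phase,
                     drop = TRUE)
  bad <- vapply(split(gaze$t, key),
                function(t) is.unsorted(t, strictly = TRUE), logical(1))
  if (any(bad))
    stop("non-monotone timestamps within series: ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  attr(gaze, "n_dropped") <- n_dropped
  gaze
}

#' Write and read synchrony tables and model traces
#'
#' Plain-CSV round-trips for the per-trial synchrony table produced by
#' [session_synchrony()] and the per-trial trace produced by
#' [run_session()].
#'
#' @param x The table to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the table
#'   (traces regain the `"model_trace"` class).
#' @export
write_sync_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sync_table
#' @export
read_sync_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "dtw_raw", "dtw_norm", "gamma_t")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stop("synchrony table is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  x
}

#' @rdname write_sync_table
#' @export
write_trace <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sync_table
#' @export
read_trace <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(x) <- c("model_trace", "data.frame")
  x
}

#' Write an evaluation report as JSON
#'
#' Serializes the scalar metrics and the trajectory table of an
#' [evaluate_trace()] report.
#'
#' @param report A report list from [evaluate_trace()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}
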