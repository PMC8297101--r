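#' Intervention event log
#'
#' The coach's memory: one row per delivery attempt with its outcome. The
#' day planner counts completions against weekly targets from it, the
#' momentary planner counts completions/rejections within the day, and the
#' acceptance model is trained from its outcomes. Serializes to an
#' append-only JSON-lines file with ISO-8601 timestamps.
#'
#' Columns: `time` (POSIXct), `date` (Date), `goal_instance_id`,
#' `tool_type`, `outcome` ("completed" or "rejected"), `reason`
#' ("completed", "declined", "left_room", "postponed"), `score` (0-100 or
#' `NA`), `requested` (logical).
#'
#' @return an empty event log data.frame.
#' @export
empty_event_log <- function() {
  data.frame(time = as.POSIXct(character(), tz = "UTC"),
             date = as.Date(character()),
             goal_instance_id = character(), tool_type = character(),
             outcome = character(), reason = character(),
             score = numeric(), requested = logical(),
             stringsAsFactors = FALSE)
}

#' Append an intervention record to the log
#'
#' @param log an event log.
#' @param record a list as produced by [handle_outcome()].
#' @return the extended log.
#' @export
log_append <- function(log, record) {
  rbind(log, data.frame(
    time = record$time, date = clock_date(record$time),
    goal_instance_id = record$goal_instance_id,
    tool_type = record$tool_type, outcome = record$outcome,
    reason = record$reason,
    score = if (is.null(record$score)) NA_real_ else record$score,
    requested = isTRUE(record$requested), stringsAsFactors = FALSE))
}

#' Write an event log as JSON lines
#'
#' @param log an event log.
#' @param path output path; one JSON object per line, ISO-8601 timestamps.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path) {
  lines <- vapply(seq_len(nrow(log)), function(i) {
    rec <- as.list(log[i, ])
    rec$time <- format(rec$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    rec$date <- format(rec$date)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                  digits = NA))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an event log from JSON lines
#'
#' @param path a file written by [write_event_log()].
#' @return an event log data.frame.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(empty_event_log())
  out <- empty_event_log()
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln)
    rec$time <- as.POSIXct(rec$time, format = "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC")
    if (is.null(rec$score)) rec$score <- NA_real_
    out <- log_append(out, rec)
  }
  out
}

# Completed interventions for a goal (optionally one tool) on a date range.
#' @keywords internal
count_completed <- function(log, goal_instance_id, from, to,
                            tool_type = NULL) {
  if (nrow(log) == 0L) return(0L)
  sel <- log$goal_instance_id == goal_instance_id &
    log$outcome == "completed" & log$date >= from & log$date <= to
  if (!is.null(tool_type)) sel <- sel & log$tool_type == tool_type
  sum(sel)
}
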