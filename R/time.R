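# Clock and calendar helpers. All timestamps are POSIXct in UTC (the
# simulator's "local wall clock"); dates are base Date; within-day times are
# minutes since local midnight. Goal weeks are calendar weeks starting Monday.

#' @keywords internal
minute_of_day <- function(clock) {
  lt <- as.POSIXlt(clock, tz = "UTC")
  lt$hour * 60L + lt$min
}

#' @keywords internal
clock_date <- function(clock) as.Date(clock, tz = "UTC")

# ISO weekday: Monday = 1 ... Sunday = 7
#' @keywords internal
iso_wday <- function(date) {
  w <- as.POSIXlt(date)$wday  # Sunday = 0
  ifelse(w == 0L, 7L, w)
}

# Monday of the calendar week containing `date`
#' @keywords internal
week_monday <- function(date) date - (iso_wday(date) - 1L)

#' Parse "HH:MM" to minutes since midnight
#' @keywords internal
parse_hm <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.integer(parts[1]) * 60L + as.integer(parts[2])
}

#' @keywords internal
format_hm <- function(min) sprintf("%02d:%02d", min %/% 60L, min %% 60L)

#' Construct a within-day time window
#'
#' Half-open `[start, end)` interval in local wall-clock minutes; windows do
#' not cross midnight.
#'
#' @param start,end "HH:MM" strings or minutes since midnight.
#' @return a `time_window` (list with integer `start`, `end` minutes).
#' @export
time_window <- function(start, end) {
  s <- if (is.character(start)) parse_hm(start) else as.integer(start)
  e <- if (is.character(end)) parse_hm(end) else as.integer(end)
  stopifnot(s >= 0L, e <= 1440L, s < e)
  structure(list(start = s, end = e), class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("[%s, %s)\n", format_hm(x$start), format_hm(x$end)))
  invisible(x)
}

#' @keywords internal
in_window <- function(window, clock) {
  if (is.null(window)) return(TRUE)
  m <- minute_of_day(clock)
  m >= window$start && m < window$end
}

#' @keywords internal
make_clock <- function(date, minute) {
  as.POSIXct(as.POSIXlt(date), tz = "UTC") + minute * 60
}
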