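#' Day plans
#'
#' Once per day the coach combines every active goal's weekly configuration
#' with the completed-intervention log into per-day targets. Monday-Wednesday
#' the weekly interventions are distributed evenly towards the weekly
#' maximum; from Thursday onwards the target keeps pushing towards the
#' maximum only while the participant has easily kept up with the pro-rated
#' minimum, and is otherwise lowered towards the minimum.
#'
#' @name day_plan
NULL

#' Weekly progress of a goal
#'
#' @param goal a `goal_instance`.
#' @param log the event log.
#' @param date the day under consideration (its completions are excluded).
#' @param tool_type restrict to one tool; default aggregates all tools of
#'   this goal-week.
#' @return list with `completed`, `weekly_min`, `weekly_max`, `elapsed_days`
#'   (full days of this goal-week before `date`) and `on_track` (`TRUE` iff
#'   `completed >= weekly_min * elapsed_days / 7`, so a vacuous minimum is
#'   always on track).
#' @export
week_progress <- function(goal, log, date, tool_type = NULL) {
  date <- as.Date(date)
  reqs <- goal_week_requirements(goal, date)
  if (!is.null(tool_type))
    reqs <- Filter(function(r) r$tool_type == tool_type, reqs)
  wmin <- sum(vapply(reqs, function(r) r$min_count, 0L))
  wmax <- sum(vapply(reqs, function(r) r$max_count, 0L))
  week_start <- max(week_monday(date), goal$start_date)
  elapsed <- as.integer(date - week_start)
  completed <- if (is.null(tool_type)) {
    count_completed(log, goal$instance_id, week_start, date - 1L)
  } else {
    count_completed(log, goal$instance_id, week_start, date - 1L, tool_type)
  }
  list(completed = completed, weekly_min = wmin, weekly_max = wmax,
       elapsed_days = elapsed, on_track = completed >= wmin * elapsed / 7)
}

# Daily bounds for one requirement given its weekly state. Shared by the
# planner and by nothing else; the test-suite oracle re-derives the same
# rules independently.
#' @keywords internal
daily_bounds <- function(weekly_min, weekly_max, completed, weekday,
                         on_track) {
  remaining_days <- 7L - weekday + 1L
  rem_max <- max(0L, weekly_max - completed)
  rem_min <- max(0L, weekly_min - completed)
  if (weekday <= 3L || on_track) {
    daily_max <- as.integer(ceiling(rem_max / remaining_days))
    daily_min <- as.integer(ceiling(rem_min / remaining_days))
  } else {
    daily_min <- daily_max <- as.integer(ceiling(rem_min / remaining_days))
  }
  list(daily_min = daily_min, daily_max = daily_max)
}

#' Generate the plan for one day
#'
#' @param active_goals list of active `goal_instance`s.
#' @param log the event log.
#' @param date a `Date`.
#' @return a `day_plan`: the date plus a list of items, one per
#'   (goal, tool) with remaining capacity. Each item carries `daily_min`,
#'   `daily_max`, the source weekly bounds, completions so far this week,
#'   and the requirement's time window and trigger condition. Items whose
#'   remaining daily capacity is zero are omitted. Goals outside their
#'   active duration contribute nothing.
#' @export
generate_day_plan <- function(active_goals, log, date) {
  date <- as.Date(date)
  weekday <- iso_wday(date)
  items <- list()
  for (goal in active_goals) {
    if (!identical(goal$status, "active")) next
    if (is.na(goal_week_index(goal, date))) next
    reqs <- goal_week_requirements(goal, date)
    for (req in reqs) {
      prog <- week_progress(goal, log, date, tool_type = req$tool_type)
      b <- daily_bounds(prog$weekly_min, prog$weekly_max, prog$completed,
                        weekday, prog$on_track)
      if (b$daily_max == 0L) next
      items[[length(items) + 1L]] <- structure(list(
        goal_instance_id = goal$instance_id,
        tool_type = req$tool_type,
        daily_min = b$daily_min, daily_max = b$daily_max,
        weekly_min = prog$weekly_min, weekly_max = prog$weekly_max,
        week_completed_so_far = prog$completed,
        time_window = req$time_window,
        trigger_condition = req$trigger_condition,
        tool_payload = req$tool_payload), class = "day_plan_item")
    }
  }
  structure(list(date = date, items = items), class = "day_plan")
}

#' @export
print.day_plan <- function(x, ...) {
  cat(sprintf("Day plan for %s (%d item(s))\n", format(x$date),
              length(x$items)))
  for (it in x$items) {
    win <- if (is.null(it$time_window)) "" else
      sprintf(" [%s-%s]", format_hm(it$time_window$start),
              format_hm(it$time_window$end))
    trg <- if (is.null(it$trigger_condition)) "" else " (triggered)"
    cat(sprintf("  %s/%s: %d-%d today (week %d/%d done)%s%s\n",
                it$goal_instance_id, it$tool_type, it$daily_min, it$daily_max,
                it$week_completed_so_far, it$weekly_max, win, trg))
  }
  invisible(x)
}

#' Serialize a day plan to JSON
#'
#' @param plan a `day_plan`.
#' @return a JSON string.
#' @export
day_plan_json <- function(plan) {
  items <- lapply(plan$items, function(it) {
    out <- it[c("goal_instance_id", "tool_type", "daily_min", "daily_max",
                "weekly_min", "weekly_max", "week_completed_so_far")]
    if (!is.null(it$time_window))
      out$time_window <- list(start = format_hm(it$time_window$start),
                              end = format_hm(it$time_window$end))
    if (!is.null(it$trigger_condition))
      out$trigger_condition <- list(all = it$trigger_condition$all)
    out
  })
  as.character(jsonlite::toJSON(list(date = format(plan$date), items = items),
                                auto_unbox = TRUE, digits = NA))
}
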