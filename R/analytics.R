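#' Goal performance analytics and motivational messaging
#'
#' Batch statistics behind the coffee-session charts (long-memory weekly
#' bars and short-memory daily bars), the motivational day-agenda
#' milestones, the three-tier day insight with guaranteed fallback, and the
#' end-of-goal difficulty suggestion. Everything is framed optimistically:
#' only positive comparisons ever become messages.
#'
#' @name analytics
NULL

bar_row <- function(period, completed, max_target, scores) {
  data.frame(period = period,
             fill_fraction = min(1, completed / max(1L, max_target)),
             mean_score = if (length(scores) == 0L) NA_real_
                          else mean(scores),
             completed = completed, max_target = max_target,
             stringsAsFactors = FALSE)
}

#' Weekly performance bars for one goal
#'
#' One bar per elapsed goal week: the fill is the number of completed
#' interventions over the week's summed maximum target (clamped to 1), the
#' colour statistic is the mean score of the completed interventions
#' (absent for empty weeks).
#'
#' @param goal a `goal_instance`.
#' @param log the event log.
#' @param date reporting day; weeks elapsed strictly before it are shown.
#' @return data.frame with columns `period`, `fill_fraction`, `mean_score`,
#'   `completed`, `max_target`.
#' @export
weekly_bars <- function(goal, log, date) {
  date <- as.Date(date)
  out <- list()
  for (w in seq_len(goal$level$duration_weeks)) {
    wk_start <- week_monday(goal$start_date) + (w - 1L) * 7L
    wk_end <- wk_start + 6L
    if (wk_start >= date) break
    ref_day <- max(wk_start, goal$start_date)
    reqs <- goal_week_requirements(goal, ref_day)
    wmax <- sum(vapply(reqs, function(r) r$max_count, 0L))
    sel <- log$goal_instance_id == goal$instance_id &
      log$outcome == "completed" & log$date >= wk_start & log$date <= wk_end
    out[[w]] <- bar_row(sprintf("week %d", w), sum(sel), wmax,
                        log$score[sel & !is.na(log$score)])
  }
  do.call(rbind, out)
}

#' Daily performance bars for one goal
#'
#' Same statistic as [weekly_bars()] at day granularity over the most
#' recent `window_days`: the denominator is the summed `daily_max` of the
#' goal's items in that day's plan (re-derived from the log as it stood
#' that morning).
#'
#' @param goal a `goal_instance`.
#' @param log the event log.
#' @param window_days how many recent days to show.
#' @param date reporting day; days strictly before it are shown.
#' @return data.frame as in [weekly_bars()].
#' @export
daily_bars <- function(goal, log, window_days, date) {
  date <- as.Date(date)
  days <- seq(date - window_days, date - 1L, by = 1L)
  days <- days[days >= goal$start_date & days <= goal_end_date(goal)]
  out <- list()
  for (d in seq_along(days)) {
    day <- days[d]
    log_before <- log[log$date < day, , drop = FALSE]
    plan <- generate_day_plan(list(goal), log_before, day)
    dmax <- sum(vapply(plan$items, function(it) it$daily_max, 0L))
    sel <- log$goal_instance_id == goal$instance_id &
      log$outcome == "completed" & log$date == day
    out[[d]] <- bar_row(format(day), sum(sel), dmax,
                        log$score[sel & !is.na(log$score)])
  }
  do.call(rbind, out)
}

#' Export chart data as CSV
#'
#' @param bars a data.frame from [weekly_bars()] or [daily_bars()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bars_csv <- function(bars, path) {
  utils::write.csv(bars[, c("period", "fill_fraction", "mean_score")],
                   path, row.names = FALSE)
  invisible(path)
}

milestone_kinds <- c("min_one_goal", "max_one_goal", "min_all_goals",
                     "max_all_goals")

#' Detect newly crossed day-plan milestones
#'
#' Four milestone kinds re-display the motivational agenda: the daily
#' minimum or maximum reached for one goal, and the daily minimum or
#' maximum reached for all active goals. Each (kind, goal, day) fires at
#' most once; the caller threads the `seen` key set between calls, so a
#' repeated call with an unchanged log yields nothing new.
#'
#' @param plan the `day_plan` of the day.
#' @param log the event log.
#' @param now POSIXct.
#' @param seen character vector of already-fired milestone keys.
#' @return list with `milestones` (list of records with `kind`,
#'   `goal_instance_id`, `timestamp`) and the updated `seen`.
#' @export
detect_milestones <- function(plan, log, now, seen = character()) {
  date <- clock_date(now)
  goals <- unique(vapply(plan$items, function(it) it$goal_instance_id, ""))
  fired <- list()
  fire <- function(kind, goal_id) {
    key <- paste(kind, if (is.na(goal_id)) "*" else goal_id, format(date),
                 sep = "|")
    if (key %in% seen) return()
    seen <<- c(seen, key)
    fired[[length(fired) + 1L]] <<- list(kind = kind,
                                         goal_instance_id = goal_id,
                                         timestamp = now)
  }
  status <- lapply(goals, function(g) {
    items <- Filter(function(it) it$goal_instance_id == g, plan$items)
    done <- vapply(items, function(it) item_today(log, it, date)$completed, 0L)
    dmin <- sum(vapply(items, function(it) it$daily_min, 0L))
    dmax <- sum(vapply(items, function(it) it$daily_max, 0L))
    list(goal = g, min_hit = dmin > 0L && sum(done) >= dmin,
         max_hit = dmax > 0L && sum(done) >= dmax)
  })
  for (s in status) {
    if (s$min_hit) fire("min_one_goal", s$goal)
    if (s$max_hit) fire("max_one_goal", s$goal)
  }
  if (length(status) > 0L) {
    if (all(vapply(status, `[[`, TRUE, "min_hit")))
      fire("min_all_goals", NA_character_)
    if (all(vapply(status, `[[`, TRUE, "max_hit")))
      fire("max_all_goals", NA_character_)
  }
  list(milestones = fired, seen = seen)
}

daily_mean_scores <- function(log, before_date) {
  sel <- log$outcome == "completed" & !is.na(log$score) &
    log$date < before_date
  if (!any(sel)) return(data.frame(date = as.Date(character()),
                                   score = numeric()))
  agg <- stats::aggregate(score ~ date, data = log[sel, , drop = FALSE],
                          FUN = mean)
  agg[order(agg$date), , drop = FALSE]
}

insight <- function(kind, text, evidence) {
  structure(list(kind = kind, text = text, evidence = evidence),
            class = "day_insight")
}

#' @export
print.day_insight <- function(x, ...) {
  cat(sprintf("[%s] %s\n", x$kind, x$text))
  invisible(x)
}

#' Generate the single day insight
#'
#' Total by construction: exactly one insight comes out of every input.
#' Precedence: a goal-performance insight when yesterday beat a historical
#' statistic (strictly best daily mean score to date, or the last-7-day
#' mean above the last-30-day mean); else a user-model insight when the
#' tracked sensing series shows a positive trend (last-7-day mean exceeding
#' the last-30-day mean by at least `cfg$insight_effect_sd` pooled standard
#' deviations); else an awareness tip drawn round-robin from the active
#' goals' tips; else a fallback message from the plugin's mandatory
#' fallback pool. Only positive comparisons ever produce performance or
#' user-model insights.
#'
#' @param goals non-empty list of active `goal_instance`s.
#' @param log the event log.
#' @param user_stats optional data.frame `date`, `value` of a tracked
#'   participant series (e.g. daily positive-emotion fraction).
#' @param date the insight day.
#' @param rng_seed seed for the fallback draw (deterministic given inputs).
#' @param cfg a [coach_config()].
#' @return a `day_insight` with `kind`, `text` and structured `evidence`.
#' @export
generate_day_insight <- function(goals, log, user_stats = NULL, date,
                                 rng_seed = 1L, cfg = coach_config()) {
  stopifnot(length(goals) >= 1L)
  date <- as.Date(date)

  daily <- daily_mean_scores(log, date)
  yesterday <- daily$score[daily$date == date - 1L]
  prior <- daily$score[daily$date < date - 1L]
  if (length(yesterday) == 1L && length(prior) > 0L &&
      yesterday > max(prior)) {
    return(insight("goal_performance",
                   "Congratulations!! Yesterday you got the overall best score in your interventions.",
                   list(statistic = "best_daily_score",
                        yesterday = yesterday, previous_best = max(prior))))
  }
  recent7 <- daily$score[daily$date >= date - 7L]
  recent30 <- daily$score[daily$date >= date - 30L]
  if (length(recent7) > 0L && length(recent30) > length(recent7) &&
      mean(recent7) > mean(recent30)) {
    return(insight("goal_performance",
                   "Great week! Your intervention scores this week beat your monthly average.",
                   list(statistic = "week_vs_month",
                        week_mean = mean(recent7),
                        month_mean = mean(recent30))))
  }
  if (!is.null(user_stats) && nrow(user_stats) > 0L) {
    s7 <- user_stats$value[user_stats$date >= date - 7L &
                             user_stats$date < date]
    s30 <- user_stats$value[user_stats$date >= date - 30L &
                              user_stats$date < date]
    sd30 <- stats::sd(s30)
    if (length(s7) > 0L && length(s30) > length(s7) &&
        !is.na(sd30) && sd30 > 0 &&
        mean(s7) - mean(s30) >= cfg$insight_effect_sd * sd30) {
      return(insight("user_model",
                     "Lately I see you being more positive. Good for you!",
                     list(statistic = "trend_vs_month", week_mean = mean(s7),
                          month_mean = mean(s30), sd = sd30)))
    }
  }
  tips <- unlist(lapply(goals, function(g) g$plugin$awareness_tips))
  if (length(tips) > 0L) {
    idx <- (as.integer(date) %% length(tips)) + 1L
    return(insight("goal_tip", tips[idx],
                   list(statistic = "round_robin_tip", index = idx)))
  }
  pool <- goals[[1L]]$plugin$fallback_messages
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(rng_seed)
  msg <- sample(pool, 1L)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  insight("fallback", msg, list(statistic = "fallback_pool"))
}

#' Suggest the next difficulty level after a finished goal
#'
#' Overall completion at or above `cfg$harder_frac` (default 80%) of the
#' summed weekly maxima suggests a harder level; below `cfg$easier_frac`
#' (default 50%) of the summed weekly minima suggests an easier one;
#' anything in between keeps the level.
#'
#' @param goal a `goal_instance` that has run its full duration.
#' @param log the event log.
#' @param cfg a [coach_config()].
#' @return one of "harder", "same", "easier".
#' @export
suggest_next_difficulty <- function(goal, log, cfg = coach_config()) {
  total_min <- 0L; total_max <- 0L
  for (w in seq_len(goal$level$duration_weeks)) {
    ref_day <- max(week_monday(goal$start_date) + (w - 1L) * 7L,
                   goal$start_date)
    reqs <- goal_week_requirements(goal, ref_day)
    total_min <- total_min + sum(vapply(reqs, function(r) r$min_count, 0L))
    total_max <- total_max + sum(vapply(reqs, function(r) r$max_count, 0L))
  }
  completed <- count_completed(log, goal$instance_id, goal$start_date,
                               goal_end_date(goal))
  if (total_max > 0L && completed >= cfg$harder_frac * total_max) "harder"
  else if (total_min > 0L && completed < cfg$easier_frac * total_min) "easier"
  else "same"
}
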