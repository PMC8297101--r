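# Independent oracle for the daily-target rules: a literal transcription
# of the distribution/Thursday policy, separate from the planner code.
oracle_bounds <- function(weekly_min, weekly_max, completed, weekday) {
  remaining_days <- 7 - weekday + 1
  rem_max <- max(0, weekly_max - completed)
  rem_min <- max(0, weekly_min - completed)
  elapsed <- weekday - 1
  on_track <- completed >= weekly_min * elapsed / 7
  if (weekday <= 3 || on_track) {
    list(daily_min = ceiling(rem_min / remaining_days),
         daily_max = ceiling(rem_max / remaining_days))
  } else {
    list(daily_min = ceiling(rem_min / remaining_days),
         daily_max = ceiling(rem_min / remaining_days))
  }
}

plan_for <- function(pl, log, date) {
  goal <- instantiate_goal(pl, "easy", MONDAY)
  generate_day_plan(list(goal), log, date)
}

test_that("Monday-Wednesday distributes evenly towards the weekly maximum", {
  pl <- simple_plugin(min_count = 3, max_count = 7)
  plan <- plan_for(pl, empty_event_log(), MONDAY)
  expect_length(plan$items, 1L)
  expect_identical(plan$items[[1]]$daily_max, as.integer(ceiling(7 / 7)))
  expect_identical(plan$items[[1]]$daily_min, as.integer(ceiling(3 / 7)))

  # Wednesday with 2 completed: remaining 5 of max over 5 days
  goal <- instantiate_goal(pl, "easy", MONDAY)
  log <- log_with_completions(goal$instance_id, c(MONDAY, MONDAY + 1))
  plan3 <- generate_day_plan(list(goal), log, MONDAY + 2)
  expect_identical(plan3$items[[1]]$daily_max, as.integer(ceiling(5 / 5)))
})

test_that("from Thursday a lagging participant is pulled towards the minimum", {
  # weekly_min 6, only 1 completed by Thursday: not on track (1 < 6*3/7)
  pl <- simple_plugin(min_count = 6, max_count = 10)
  goal <- instantiate_goal(pl, "easy", MONDAY)
  log <- log_with_completions(goal$instance_id, MONDAY)
  thu <- MONDAY + 3
  prog <- week_progress(goal, log, thu)
  expect_false(prog$on_track)
  plan <- generate_day_plan(list(goal), log, thu)
  expect_identical(plan$items[[1]]$daily_min, as.integer(ceiling(5 / 4)))
  expect_identical(plan$items[[1]]$daily_max, as.integer(ceiling(5 / 4)))

  # on-track participant keeps being pushed towards the maximum
  log_ok <- log_with_completions(goal$instance_id,
                                 c(MONDAY, MONDAY + 1, MONDAY + 2))
  prog_ok <- week_progress(goal, log_ok, thu)
  expect_true(prog_ok$on_track)  # 3 >= 6*3/7 = 2.57
  plan_ok <- generate_day_plan(list(goal), log_ok, thu)
  expect_identical(plan_ok$items[[1]]$daily_max, as.integer(ceiling(7 / 4)))
})

test_that("a vacuous weekly minimum is always on track", {
  pl <- simple_plugin(min_count = 0, max_count = 5)
  goal <- instantiate_goal(pl, "easy", MONDAY)
  for (d in 0:6) {
    expect_true(week_progress(goal, empty_event_log(), MONDAY + d)$on_track)
  }
})

test_that("exhausted and out-of-duration items are omitted", {
  pl <- simple_plugin(min_count = 2, max_count = 3, weeks = 4)
  goal <- instantiate_goal(pl, "easy", MONDAY)
  log <- log_with_completions(goal$instance_id, rep(MONDAY, 3))
  plan <- generate_day_plan(list(goal), log, MONDAY + 1)
  expect_length(plan$items, 0L)  # weekly_max reached

  # outside the goal duration the goal contributes nothing
  plan_out <- generate_day_plan(list(goal), empty_event_log(), MONDAY + 60)
  expect_length(plan_out$items, 0L)
  # dropped goals contribute nothing either
  dropped <- set_goal_status(goal, "dropped")
  expect_length(generate_day_plan(list(dropped), empty_event_log(),
                                  MONDAY)$items, 0L)
  # empty goal list yields an empty plan, not an error
  expect_length(generate_day_plan(list(), empty_event_log(), MONDAY)$items, 0L)
})

test_that("planner matches the brute-force oracle over the full small grid", {
  tool <- "quiz"
  for (weekly_max in 0:10) {
    for (weekly_min in 0:weekly_max) {
      pl <- simple_plugin(min_count = weekly_min, max_count = weekly_max)
      goal <- instantiate_goal(pl, "easy", MONDAY)
      for (weekday in 1:7) {
        date <- MONDAY + (weekday - 1)
        for (completed in 0:min(weekly_max + 2, 12)) {
          dates <- if (completed > 0)
            rep(MONDAY + ((seq_len(completed) - 1) %% max(1, weekday - 1)),
                length.out = completed)
          else as.Date(character())
          dates <- dates[dates < date]
          if (length(dates) < completed) {
            # completions cannot precede the day on a Monday; skip infeasible
            next
          }
          log <- log_with_completions(goal$instance_id, dates, tool)
          plan <- generate_day_plan(list(goal), log, date)
          exp <- oracle_bounds(weekly_min, weekly_max, completed, weekday)
          if (exp$daily_max == 0) {
            expect_length(plan$items, 0L)
          } else {
            expect_length(plan$items, 1L)
            it <- plan$items[[1]]
            expect_identical(it$daily_max, as.integer(exp$daily_max))
            expect_identical(it$daily_min, as.integer(exp$daily_min))
            expect_identical(it$week_completed_so_far, as.integer(completed))
          }
        }
      }
    }
  }
})

test_that("weekly conservation: daily targets never overshoot the weekly max
           and meeting every daily minimum reaches the weekly minimum", {
  grid <- expand.grid(weekly_min = c(0, 2, 3, 5, 7),
                      weekly_max = c(0, 2, 3, 5, 7, 10))
  grid <- grid[grid$weekly_min <= grid$weekly_max, ]
  for (i in seq_len(nrow(grid))) {
    wmin <- grid$weekly_min[i]; wmax <- grid$weekly_max[i]
    pl <- simple_plugin(min_count = wmin, max_count = wmax)
    goal <- instantiate_goal(pl, "easy", MONDAY)

    # participant completes exactly daily_max each day
    dates_done <- as.Date(character())
    for (d in 0:6) {
      lg <- log_with_completions(goal$instance_id, dates_done)
      plan <- generate_day_plan(list(goal), lg, MONDAY + d)
      dmax <- if (length(plan$items) > 0) plan$items[[1]]$daily_max else 0
      dates_done <- c(dates_done, rep(MONDAY + d, dmax))
    }
    expect_lte(length(dates_done), wmax)

    # participant completes exactly daily_min each day
    dates_min <- as.Date(character())
    for (d in 0:6) {
      lg <- log_with_completions(goal$instance_id, dates_min)
      plan <- generate_day_plan(list(goal), lg, MONDAY + d)
      dmin <- if (length(plan$items) > 0) plan$items[[1]]$daily_min else 0
      dates_min <- c(dates_min, rep(MONDAY + d, dmin))
    }
    expect_gte(length(dates_min), wmin)
  }
})

test_that("completions only shrink the item's remaining capacity", {
  # intra-day: bounds are frozen at plan generation and today's
  # completions monotonically consume the remaining daily capacity
  pl <- simple_plugin(min_count = 3, max_count = 8)
  goal <- instantiate_goal(pl, "easy", MONDAY)
  for (weekday in c(2, 4, 6)) {
    date <- MONDAY + (weekday - 1)
    lg_morning <- log_with_completions(goal$instance_id,
                                       rep(MONDAY, min(2, weekday - 1)))
    plan <- generate_day_plan(list(goal), lg_morning, date)
    if (length(plan$items) == 0) next
    it <- plan$items[[1]]
    clock <- make_test_clock(date, 600)
    p <- present_state(clock); e <- sunny(clock)
    lg <- lg_morning
    prev_remaining <- it$daily_max
    for (k in seq_len(it$daily_max)) {
      lg <- log_with_completions(goal$instance_id,
                                 c(lg$date, date))
      remaining <- it$daily_max -
        sum(lg$date == date & lg$tool_type == it$tool_type)
      expect_lt(remaining, prev_remaining)
      prev_remaining <- remaining
    }
    # at zero remaining capacity the item is no longer eligible
    expect_length(filter_eligible(plan, p, e, clock, lg), 0L)
  }

  # across days within the Monday-Wednesday even-distribution phase the
  # regenerated daily_max is likewise non-increasing in completions
  for (completed in 0:7) {
    lg1 <- log_with_completions(goal$instance_id, rep(MONDAY, completed))
    lg2 <- log_with_completions(goal$instance_id, rep(MONDAY, completed + 1))
    p1 <- generate_day_plan(list(goal), lg1, MONDAY + 1)
    p2 <- generate_day_plan(list(goal), lg2, MONDAY + 1)
    m1 <- if (length(p1$items) > 0) p1$items[[1]]$daily_max else 0L
    m2 <- if (length(p2$items) > 0) p2$items[[1]]$daily_max else 0L
    expect_lte(m2, m1)
  }
})

test_that("day plans serialize to JSON with their windows and triggers", {
  pl <- load_goal_plugin(fixture_plugin_path())
  goal <- instantiate_goal(pl, "easy", MONDAY)
  plan <- generate_day_plan(list(goal), empty_event_log(), MONDAY)
  js <- jsonlite::fromJSON(day_plan_json(plan), simplifyVector = FALSE)
  expect_identical(js$date, format(MONDAY))
  expect_length(js$items, length(plan$items))
  rec <- js$items[[2]]
  expect_identical(rec$time_window$start, "10:00")
  expect_identical(rec$trigger_condition$all[[1]]$field,
                   "interacting_object")
})
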