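#' Session-level coach state and cadence
#'
#' Glues the timescales together: the weekly coffee session (review/join/
#' preview), the daily agenda-and-insight delivery on first detection, the
#' momentary loop on every state change, and the bookkeeping the momentary
#' planner needs (last delivery time, previous tool, consecutive vetoes,
#' fired milestones).
#'
#' @name orchestrator
NULL

#' Create a coach state
#'
#' @param goals list of `goal_instance`s.
#' @param config a [coach_config()].
#' @return a `coach_state`.
#' @export
coach_state <- function(goals = list(), config = coach_config()) {
  structure(list(goals = goals, log = empty_event_log(),
                 model = acceptance_model(config),
                 last_coffee_date = NULL, last_delivery_time = NULL,
                 consecutive_vetoes = 0L, previous_tool = NULL,
                 agenda_date = NULL, plan = NULL,
                 milestone_seen = character(), user_stats = NULL,
                 config = config),
            class = "coach_state")
}

#' @export
print.coach_state <- function(x, ...) {
  active <- sum(vapply(x$goals, function(g) g$status == "active", TRUE))
  cat(sprintf("Coach state: %d goal(s) (%d active), %d logged outcome(s)\n",
              length(x$goals), active, nrow(x$log)))
  cat(sprintf("  last coffee: %s; consecutive vetoes: %d\n",
              if (is.null(x$last_coffee_date)) "never"
              else format(x$last_coffee_date), x$consecutive_vetoes))
  invisible(x)
}

active_goals <- function(state)
  Filter(function(g) g$status == "active", state$goals)

#' Should a coffee session start now?
#'
#' True when at least 7 days have passed since the last coffee (or none has
#' ever happened), when the participant has no active goals (the session
#' is then launched automatically), or when the participant explicitly
#' requested it.
#'
#' @param state a `coach_state`.
#' @param clock POSIXct now; the participant must be present.
#' @param requested did the participant ask for the coffee session?
#' @return logical.
#' @export
maybe_start_coffee <- function(state, clock, requested = FALSE) {
  if (isTRUE(requested)) return(TRUE)
  if (length(active_goals(state)) == 0L) return(TRUE)
  if (is.null(state$last_coffee_date)) return(TRUE)
  as.integer(clock_date(clock) - state$last_coffee_date) >= 7L
}

#' Run a coffee session
#'
#' The fixed three-step weekly session: (1) review the active goals one by
#' one — each review shows the long-memory weekly bars and short-memory
#' daily bars, can be skipped, and may drop the goal; a goal past its full
#' duration is marked completed and gets a difficulty suggestion;
#' (2) join new goals from the catalogue (the plugin's display-only
#' joining requirements are surfaced in the report); (3) preview the
#' aggregated targets of next week across all active goals.
#'
#' @param state a `coach_state`.
#' @param decisions scripted or simulated participant choices: a list with
#'   optional `review` (named character vector/list mapping instance ids to
#'   "keep", "skip" or "drop") and `join` (list of `list(plugin, level)`).
#' @param clock POSIXct now.
#' @return list with the updated `state` and a session `report`
#'   (per-goal reviews with charts and suggestions, drops, joins with
#'   requirement text, and the next-week preview).
#' @export
run_coffee_session <- function(state, decisions = list(), clock) {
  date <- clock_date(clock)
  report <- list(reviews = list(), joined = list(), preview = NULL)

  for (i in seq_along(state$goals)) {
    g <- state$goals[[i]]
    if (g$status != "active") next
    choice <- decisions$review[[g$instance_id]]
    if (is.null(choice)) choice <- "keep"
    rev <- list(goal = g$instance_id, choice = choice)
    if (choice != "skip") {
      rev$weekly <- weekly_bars(g, state$log, date)
      rev$daily <- daily_bars(g, state$log, 7L, date)
    }
    if (choice == "drop") {
      state$goals[[i]] <- set_goal_status(g, "dropped")
    } else if (goal_end_date(g) < date) {
      rev$suggestion <- suggest_next_difficulty(g, state$log, state$config)
      state$goals[[i]] <- set_goal_status(g, "completed")
    }
    report$reviews[[g$instance_id]] <- rev
  }

  for (j in decisions$join) {
    inst <- instantiate_goal(j$plugin, j$level, date)
    state$goals[[length(state$goals) + 1L]] <- inst
    report$joined[[inst$instance_id]] <-
      list(goal = inst$instance_id,
           requirements = j$plugin$requirements)  # surfaced at join time
  }

  next_monday <- week_monday(date) + 7L
  preview <- list()
  for (g in active_goals(state)) {
    if (is.na(goal_week_index(g, next_monday))) next
    for (req in goal_week_requirements(g, next_monday)) {
      preview[[length(preview) + 1L]] <- data.frame(
        goal_instance_id = g$instance_id, tool_type = req$tool_type,
        weekly_min = req$min_count, weekly_max = req$max_count,
        stringsAsFactors = FALSE)
    }
  }
  report$preview <- if (length(preview) > 0L) do.call(rbind, preview)

  state$last_coffee_date <- date
  list(state = state, report = report)
}

# Ad-hoc item for a speech-requested tool absent from today's plan (the
# request is honoured as an extra; daily bounds stay untouched).
request_extra_item <- function(tool_type, goal_id = "request") {
  structure(list(goal_instance_id = goal_id, tool_type = tool_type,
                 daily_min = 0L, daily_max = .Machine$integer.max,
                 weekly_min = 0L, weekly_max = .Machine$integer.max,
                 week_completed_so_far = 0L, time_window = NULL,
                 trigger_condition = NULL, tool_payload = NULL),
            class = "day_plan_item")
}

#' React to a participant detection or state change
#'
#' On the first detection of the day: regenerate the day plan and emit the
#' day agenda followed by the day insight, before any other intervention.
#' On every event (including the first), run the momentary loop: filter
#' the plan, rank, and decide. A coffee session due by cadence is also
#' started here. Milestone crossings re-display the agenda; they are
#' detected when outcomes are recorded ([record_outcome()]).
#'
#' @param state a `coach_state`.
#' @param p a `participant_state` (present).
#' @param e an `environment_state`.
#' @param clock POSIXct now.
#' @param requested_tool tool type requested by speech command, or `NULL`.
#' @param coffee_decisions scripted choices for an auto-started coffee
#'   session (default: review everything, join nothing).
#' @return list with the ordered `actions` (each `list(action, detail)`),
#'   the momentary `decision` (a `delivery_decision` augmented with
#'   `features` and `requested`, or `NULL`) and the updated `state`.
#' @export
on_participant_detected <- function(state, p, e, clock,
                                    requested_tool = NULL,
                                    coffee_decisions = list()) {
  stopifnot(isTRUE(p$present))
  date <- clock_date(clock)
  actions <- list()

  first_today <- is.null(state$agenda_date) || state$agenda_date != date
  if (first_today) {
    state$plan <- generate_day_plan(active_goals(state), state$log, date)
    state$agenda_date <- date
    actions[[length(actions) + 1L]] <-
      list(action = "agenda",
           detail = sprintf("%d item(s)", length(state$plan$items)))
    if (length(active_goals(state)) > 0L) {
      ins <- generate_day_insight(active_goals(state), state$log,
                                  state$user_stats, date,
                                  rng_seed = as.integer(date),
                                  cfg = state$config)
      actions[[length(actions) + 1L]] <-
        list(action = "insight", detail = ins$kind)
      state$last_insight <- ins
    }
  }

  if (maybe_start_coffee(state, clock)) {
    cs <- run_coffee_session(state, coffee_decisions, clock)
    state <- cs$state
    state$last_coffee_report <- cs$report
    # replan if the session changed the goal set
    state$plan <- generate_day_plan(active_goals(state), state$log, date)
    actions[[length(actions) + 1L]] <- list(action = "coffee",
                                            detail = "cadence")
  }

  decision <- NULL
  if (!is.null(state$plan)) {
    eligible <- filter_eligible(state$plan, p, e, clock, state$log)
    if (!is.null(requested_tool) &&
        !requested_tool %in% vapply(eligible, `[[`, "", "tool_type")) {
      extra_goal <- if (length(active_goals(state)) > 0L)
        active_goals(state)[[1L]]$instance_id else "request"
      eligible <- c(eligible, list(request_extra_item(requested_tool,
                                                      extra_goal)))
    }
    sel <- select_intervention(eligible, clock, state$log,
                               previous_tool = state$previous_tool,
                               requested_tool = requested_tool)
    if (!is.null(sel)) {
      hist <- history_from_log(state$log, sel$item$tool_type, clock)
      feats <- extract_features(p, e, clock, hist, sel$item$tool_type,
                                state$config$vocab)
      decision <- should_deliver(sel, state$last_delivery_time, clock,
                                 model = state$model, features = feats,
                                 consecutive_vetoes = state$consecutive_vetoes,
                                 cfg = state$config)
      decision$features <- feats
      decision$requested <- isTRUE(sel$inputs$participant_requested)
      decision$alt_tools <- setdiff(
        unique(vapply(eligible, `[[`, "", "tool_type")),
        sel$item$tool_type)
      if (decision$action == "skip_ml_veto")
        state$consecutive_vetoes <- state$consecutive_vetoes + 1L
    }
  }

  list(actions = actions, decision = decision, state = state)
}

#' Record a delivery outcome into the coach state
#'
#' Appends the intervention record to the event log, feeds the labelled
#' outcome to the acceptance model (running the periodic feature-selection
#' refresh), resets the veto counter, updates the last-delivery bookkeeping
#' and detects any newly crossed milestones of today's plan.
#'
#' @param state a `coach_state`.
#' @param rec a record from [handle_outcome()].
#' @param features the delivery-time [extract_features()] vector.
#' @param clock POSIXct now.
#' @return list with the updated `state` and the newly crossed
#'   `milestones`.
#' @export
record_outcome <- function(state, rec, features, clock) {
  state$log <- log_append(state$log, rec)
  state$model <- update(state$model, features, rec$accepted)
  state$model <- refresh_feature_selection(state$model, state$config)
  state$last_delivery_time <- clock
  state$previous_tool <- rec$tool_type
  state$consecutive_vetoes <- 0L
  milestones <- list()
  if (!is.null(state$plan) && identical(state$plan$date, clock_date(clock))) {
    ms <- detect_milestones(state$plan, state$log, clock,
                            state$milestone_seen)
    state$milestone_seen <- ms$seen
    milestones <- ms$milestones
  }
  list(state = state, milestones = milestones)
}
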