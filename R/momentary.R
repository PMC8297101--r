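#' Momentary planning
#'
#' The event-driven core: on every participant-state change the coach
#' (a) filters the day plan down to the interventions launchable right now,
#' (b) ranks them with a fixed linear priority heuristic and picks the top
#' one, and (c) decides whether this is a good moment to deliver it, based
#' on the time elapsed since the last intervention (insistence scales with
#' priority) and on the acceptance model's prediction, whose veto is capped
#' at a configurable number of consecutive uses.
#'
#' @name momentary_planner
NULL

# Weights of the priority ranking linear combination (fixed, obtained
# empirically with domain partners; see the methods vignette).
rank_weights <- c(requested = 1.1, not_min = 0.6, not_prev = 0.2,
                  requires_cond = 0.1, urgency = 0.06, shortfall = 0.04)

#' Accomplishment rate
#'
#' 1 when the carried-out interventions have reached the minimum target,
#' otherwise `carried_out / minimum_target`. A zero minimum target is
#' vacuously met, so the rate is 1 (avoids 0/0 and agrees with the first
#' branch).
#'
#' @param carried_out non-negative count of carried-out interventions.
#' @param minimum_target non-negative minimum target.
#' @return a value in `[0, 1]`.
#' @export
accomplishment_rate <- function(carried_out, minimum_target) {
  stopifnot(carried_out >= 0, minimum_target >= 0)
  if (carried_out >= minimum_target) 1 else carried_out / minimum_target
}

#' Ranking inputs
#'
#' The symbolic inputs of the priority ranking for one candidate
#' intervention. Booleans are coded 1/0.
#'
#' @param participant_requested was this tool explicitly requested by
#'   speech command?
#' @param not_min_reached has the minimum target *not* been reached yet?
#' @param not_previous was this *not* the previously delivered tool?
#' @param requires_condition does the intervention carry a trigger
#'   condition?
#' @param remaining_time time left in the launch window (same units as
#'   `time_range`); `0 <= remaining_time <= time_range`.
#' @param time_range total length of the launch window, positive.
#' @param carried_out,minimum_target counts feeding
#'   [accomplishment_rate()].
#' @return a `ranking_inputs`.
#' @export
ranking_inputs <- function(participant_requested = FALSE,
                           not_min_reached = FALSE, not_previous = TRUE,
                           requires_condition = FALSE,
                           remaining_time = 1, time_range = 1,
                           carried_out = 0L, minimum_target = 0L) {
  stopifnot(time_range > 0, remaining_time >= 0,
            remaining_time <= time_range)
  structure(list(participant_requested = isTRUE(participant_requested),
                 not_min_reached = isTRUE(not_min_reached),
                 not_previous = isTRUE(not_previous),
                 requires_condition = isTRUE(requires_condition),
                 remaining_time = remaining_time, time_range = time_range,
                 carried_out = carried_out, minimum_target = minimum_target),
            class = "ranking_inputs")
}

#' Priority ranking of a candidate intervention
#'
#' The fixed linear combination
#' `1.1 * participant_requested + 0.6 * not_min_reached +
#'  0.2 * not_previous + 0.1 * requires_condition +
#'  0.06 * (1 - remaining_time / time_range) +
#'  0.04 * (1 - accomplishment_rate)`,
#' with booleans coded 1/0. Direct participant requests dominate every
#' other term combined; unmet minima come next; repeating the previous tool
#' is penalised; condition-triggered tools get a small boost; and closing
#' launch windows plus low accomplishment add urgency.
#'
#' @param inp a [ranking_inputs()].
#' @return the priority score (max 2.1).
#' @export
priority_rank <- function(inp) {
  rate <- accomplishment_rate(inp$carried_out, inp$minimum_target)
  unname(rank_weights["requested"] * inp$participant_requested +
         rank_weights["not_min"] * inp$not_min_reached +
         rank_weights["not_prev"] * inp$not_previous +
         rank_weights["requires_cond"] * inp$requires_condition +
         rank_weights["urgency"] * (1 - inp$remaining_time / inp$time_range) +
         rank_weights["shortfall"] * (1 - rate))
}

# Completions/rejections of one plan item today, from the log.
#' @keywords internal
item_today <- function(log, item, date) {
  if (nrow(log) == 0L) return(list(completed = 0L, delivered = 0L))
  sel <- log$goal_instance_id == item$goal_instance_id &
    log$tool_type == item$tool_type & log$date == date
  list(completed = sum(sel & log$outcome == "completed"),
       delivered = sum(sel))
}

#' Filter the day plan down to launchable items
#'
#' Retains an item iff its completions today are below `daily_max`, the
#' clock falls inside its time window (if any) and its trigger condition
#' (if any) holds in the current state.
#'
#' @param plan a `day_plan`.
#' @param p a `participant_state`; must be present.
#' @param e an `environment_state`.
#' @param clock POSIXct now.
#' @param log the event log (for completions today).
#' @return the eligible subset of `plan$items`.
#' @export
filter_eligible <- function(plan, p, e, clock, log) {
  stopifnot(isTRUE(p$present))
  date <- clock_date(clock)
  Filter(function(item) {
    if (item_today(log, item, date)$completed >= item$daily_max) return(FALSE)
    if (!in_window(item$time_window, clock)) return(FALSE)
    eval_condition(item$trigger_condition, p, e, clock)
  }, plan$items)
}

# Ranking inputs for a plan item in context. Items without an explicit
# window use the remainder of the day as their launch window.
#' @keywords internal
item_ranking_inputs <- function(item, clock, log, previous_tool = NULL,
                                requested_tool = NULL) {
  date <- clock_date(clock)
  today <- item_today(log, item, date)
  m <- minute_of_day(clock)
  if (is.null(item$time_window)) {
    range <- 1440; remaining <- 1440 - m
  } else {
    range <- item$time_window$end - item$time_window$start
    remaining <- max(0, item$time_window$end - m)
  }
  remaining <- min(remaining, range)
  ranking_inputs(
    participant_requested = !is.null(requested_tool) &&
      identical(requested_tool, item$tool_type),
    not_min_reached = today$completed < item$daily_min,
    not_previous = !identical(previous_tool, item$tool_type),
    requires_condition = !is.null(item$trigger_condition),
    remaining_time = remaining, time_range = range,
    carried_out = today$completed, minimum_target = item$daily_min)
}

#' Select the most suitable intervention
#'
#' Scores every eligible item with [priority_rank()] and returns the
#' maximum. Exact ties go to the item with fewer completions today, then to
#' the lexicographically smallest tool type (deterministic for testing).
#'
#' Repeating the previously delivered tool type is a hard user-friendly
#' restriction, not only the 0.2 ranking term: when a different eligible
#' tool exists, items of the previous tool are excluded from the ranking
#' (a direct participant request is exempt). The 0.2 term still orders the
#' remaining candidates.
#'
#' @param eligibles list of eligible `day_plan_item`s.
#' @param clock POSIXct now.
#' @param log the event log.
#' @param previous_tool tool type of the previous delivery, or `NULL`.
#' @param requested_tool tool type requested by speech command, or `NULL`.
#' @return `NULL` when `eligibles` is empty, else a list with `item`,
#'   `score` and the `inputs` used.
#' @export
select_intervention <- function(eligibles, clock, log, previous_tool = NULL,
                                requested_tool = NULL) {
  if (length(eligibles) == 0L) return(NULL)
  if (!is.null(previous_tool)) {
    tools <- vapply(eligibles, `[[`, "", "tool_type")
    keep <- tools != previous_tool
    if (!is.null(requested_tool)) keep <- keep | tools == requested_tool
    if (any(keep) && !all(keep)) eligibles <- eligibles[keep]
  }
  date <- clock_date(clock)
  scored <- lapply(eligibles, function(item) {
    inp <- item_ranking_inputs(item, clock, log, previous_tool,
                               requested_tool)
    list(item = item, score = priority_rank(inp), inputs = inp,
         completed_today = item_today(log, item, date)$completed)
  })
  ord <- order(-vapply(scored, `[[`, 0, "score"),
               vapply(scored, `[[`, 0L, "completed_today"),
               vapply(scored, function(s) s$item$tool_type, ""))
  scored[[ord[1L]]][c("item", "score", "inputs")]
}

#' Decide whether to deliver the selected intervention now
#'
#' Three gates, in order: a directly requested intervention is delivered
#' immediately (its 1.1 ranking weight alone outranks all other terms
#' combined, so requests bypass both remaining gates); otherwise the time
#' since the last delivery must reach the wait bracket of the item's
#' priority score (the coach is more insistent for higher priorities);
#' otherwise a warm acceptance model predicting a rejection may postpone
#' the delivery, but never more than `cfg$max_vetoes` times in a row.
#'
#' @param selected result of [select_intervention()].
#' @param last_delivery_time POSIXct of the previous delivery, or `NULL`.
#' @param clock POSIXct now.
#' @param model an `acceptance_model` (or `NULL` to skip the veto gate).
#' @param features the [extract_features()] vector for this candidate
#'   (needed only when `model` is given).
#' @param consecutive_vetoes current consecutive veto count.
#' @param cfg a [coach_config()].
#' @return a `delivery_decision`: `action` ("deliver", "wait" or
#'   "skip_ml_veto"), the chosen `item`, `score`, and `reason` codes.
#' @export
should_deliver <- function(selected, last_delivery_time, clock,
                           model = NULL, features = NULL,
                           consecutive_vetoes = 0L, cfg = coach_config()) {
  decision <- function(action, reason)
    structure(list(action = action, item = selected$item,
                   score = selected$score, reason = reason),
              class = "delivery_decision")
  if (isTRUE(selected$inputs$participant_requested))
    return(decision("deliver", "participant_requested"))
  if (!is.null(last_delivery_time)) {
    gap <- as.numeric(difftime(clock, last_delivery_time, units = "mins"))
    if (gap < wait_for_score(selected$score, cfg))
      return(decision("wait", "inter_intervention_wait"))
  }
  if (!is.null(model) && model_is_warm(model, cfg) &&
      consecutive_vetoes < cfg$max_vetoes) {
    p <- predict(model, features)
    if (p < cfg$veto_threshold)
      return(decision("skip_ml_veto", sprintf("predicted_reject_p=%.3f", p)))
  }
  decision("deliver", "wait_elapsed")
}

#' @export
print.delivery_decision <- function(x, ...) {
  cat(sprintf("Decision: %s %s/%s (score %.3f; %s)\n", x$action,
              x$item$goal_instance_id, x$item$tool_type, x$score, x$reason))
  invisible(x)
}

#' Record the outcome of a delivery
#'
#' Maps what happened during an in-progress intervention to an
#' intervention record: explicit completion carries the tool's score;
#' an explicit decline is a rejection; leaving the room mid-intervention
#' is a rejection (the intervention returns to the pending pool and can be
#' launched again later); so is a postponement.
#'
#' @param delivery list with `goal_instance_id`, `tool_type`, `requested`.
#' @param outcome one of "completed", "declined", "left_room", "postponed".
#' @param time POSIXct of the outcome.
#' @param score tool score in `[0, 100]` for completed outcomes.
#' @return an intervention record (list) ready for [log_append()] and for
#'   labelling the acceptance model (`accepted` field).
#' @export
handle_outcome <- function(delivery, outcome, time, score = NA_real_) {
  outcome <- match.arg(outcome,
                       c("completed", "declined", "left_room", "postponed"))
  list(time = time,
       goal_instance_id = delivery$goal_instance_id,
       tool_type = delivery$tool_type,
       outcome = if (outcome == "completed") "completed" else "rejected",
       reason = outcome,
       score = if (outcome == "completed") score else NA_real_,
       requested = isTRUE(delivery$requested),
       accepted = outcome == "completed")
}
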