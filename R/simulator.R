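#' Synthetic participant and closed-loop harness
#'
#' Emulates the *outputs* of the home sensing stack — presence blocks, room
#' and posture transitions, object interactions, a two-state emotion Markov
#' chain, daily weather — plus probabilistic accept/reject behaviour with
#' known ground-truth preference weights, so every decision module can be
#' exercised end to end without hardware or human data. No attempt is made
#' to model sensor noise or recognition errors.
#'
#' @name simulator
NULL

#' Configure a synthetic participant
#'
#' @param presence list of 7 elements (Monday..Sunday), each a list of
#'   `c(start, end)` "HH:MM" pairs of non-overlapping at-home intervals.
#'   The default is home 09:00-21:00 every day.
#' @param rooms room labels walked between.
#' @param room_change_prob per-tick probability of moving room.
#' @param postures posture labels.
#' @param posture_change_prob per-tick probability of changing posture.
#' @param objects objects occasionally interacted with ("none" implicit).
#' @param object_prob per-tick probability of touching an object.
#' @param emotion_transition 2x2 row-stochastic matrix over
#'   (positive, negative), stepped once per tick.
#' @param weather_levels,weather_probs daily weather draw.
#' @param accept_base_rate acceptance probability when all ground-truth
#'   weights are zero and no fatigue has accumulated.
#' @param accept_weights named numeric vector of ground-truth logistic
#'   weights. Names are either numeric context features (`hour` — hours
#'   from midday, `minutes_since_last` — scaled by 60, `rejections_today`)
#'   or `"feature=level"` indicators (e.g. `"room=kitchen"`).
#' @param fatigue_decrement acceptance probability lost per intervention
#'   already accepted today.
#' @param leave_prob probability that an accepted intervention is abandoned
#'   by leaving the room (counts as a rejection).
#' @param request_rate per-tick probability of a speech-command request for
#'   a random plan tool.
#' @param tick_minutes simulated clock step.
#' @param seed RNG seed for the state stream.
#' @return a `sim_participant_config`.
#' @export
sim_participant_config <- function(
    presence = rep(list(list(c("09:00", "21:00"))), 7),
    rooms = c("living_room", "kitchen", "bedroom"),
    room_change_prob = 0.1,
    postures = c("sitting", "standing", "walking"),
    posture_change_prob = 0.2,
    objects = c("sofa", "fridge", "table", "tv"),
    object_prob = 0.1,
    emotion_transition = matrix(c(0.9, 0.1, 0.3, 0.7), 2, byrow = TRUE,
                                dimnames = list(c("positive", "negative"),
                                                c("positive", "negative"))),
    weather_levels = c("sunny", "cloudy", "rainy"),
    weather_probs = c(0.5, 0.3, 0.2),
    accept_base_rate = 0.7,
    accept_weights = c(),
    fatigue_decrement = 0.02,
    leave_prob = 0.05,
    request_rate = 0.0,
    tick_minutes = 5L,
    seed = 1L) {
  stopifnot(length(presence) == 7L,
            all(dim(emotion_transition) == c(2L, 2L)),
            all(abs(rowSums(emotion_transition) - 1) < 1e-9),
            accept_base_rate >= 0, accept_base_rate <= 1,
            leave_prob >= 0, leave_prob <= 1)
  for (day in presence) {
    if (length(day) > 1L) {
      iv <- t(vapply(day, function(b) c(parse_hm(b[1]), parse_hm(b[2])),
                     c(0, 0)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
        stop("presence intervals must be non-overlapping")
    }
  }
  structure(list(presence = presence, rooms = rooms,
                 room_change_prob = room_change_prob, postures = postures,
                 posture_change_prob = posture_change_prob,
                 objects = objects, object_prob = object_prob,
                 emotion_transition = emotion_transition,
                 weather_levels = weather_levels,
                 weather_probs = weather_probs,
                 accept_base_rate = accept_base_rate,
                 accept_weights = accept_weights,
                 fatigue_decrement = fatigue_decrement,
                 leave_prob = leave_prob, request_rate = request_rate,
                 tick_minutes = as.integer(tick_minutes), seed = seed),
            class = "sim_participant_config")
}

#' Simulate the participant/environment state stream
#'
#' Seeded and reproducible. The clock advances in `tick_minutes` steps
#' inside the configured presence blocks; the participant is never present
#' outside them.
#'
#' @param cfg a [sim_participant_config()].
#' @param days number of simulated days.
#' @param start_date first simulated day.
#' @return data.frame of ticks: `time`, `present`, `room`, `posture`,
#'   `interacting_object`, `emotion`, `weather`, `speech_request`
#'   (requested tool or `NA`), `room_since`, `posture_since`.
#' @export
simulate_participant <- function(cfg, days,
                                 start_date = as.Date("2021-06-07")) {
  set.seed(cfg$seed)
  start_date <- as.Date(start_date)
  acc <- list(time = numeric(), room = character(), posture = character(),
              interacting_object = character(), emotion = character(),
              weather = character(), speech_request = character(),
              room_since = numeric(), posture_since = numeric())
  emotion <- "positive"
  for (d in seq_len(days) - 1L) {
    date <- start_date + d
    weather <- sample(cfg$weather_levels, 1L, prob = cfg$weather_probs)
    blocks <- cfg$presence[[iso_wday(date)]]
    room <- sample(cfg$rooms, 1L)
    posture <- sample(cfg$postures, 1L)
    for (b in blocks) {
      t0 <- parse_hm(b[1]); t1 <- parse_hm(b[2])
      mins <- seq(t0, t1 - 1L, by = cfg$tick_minutes)
      n <- length(mins)
      times <- as.numeric(make_clock(date, t0)) + (mins - t0) * 60
      room_since <- posture_since <- times[1L]
      rooms <- postures <- objects <- emotions <- requests <- character(n)
      rsince <- psince <- numeric(n)
      for (k in seq_len(n)) {
        now <- times[k]
        if (stats::runif(1) < cfg$room_change_prob) {
          room <- sample(setdiff(cfg$rooms, room), 1L)
          room_since <- now
        }
        if (stats::runif(1) < cfg$posture_change_prob) {
          posture <- sample(setdiff(cfg$postures, posture), 1L)
          posture_since <- now
        }
        objects[k] <- if (stats::runif(1) < cfg$object_prob)
          sample(cfg$objects, 1L) else NA_character_
        emotion <- sample(colnames(cfg$emotion_transition), 1L,
                          prob = cfg$emotion_transition[emotion, ])
        emotions[k] <- emotion
        requests[k] <- if (stats::runif(1) < cfg$request_rate) "?"
          else NA_character_
        rooms[k] <- room; postures[k] <- posture
        rsince[k] <- room_since; psince[k] <- posture_since
      }
      acc$time <- c(acc$time, times)
      acc$room <- c(acc$room, rooms)
      acc$posture <- c(acc$posture, postures)
      acc$interacting_object <- c(acc$interacting_object, objects)
      acc$emotion <- c(acc$emotion, emotions)
      acc$weather <- c(acc$weather, rep(weather, n))
      acc$speech_request <- c(acc$speech_request, requests)
      acc$room_since <- c(acc$room_since, rsince)
      acc$posture_since <- c(acc$posture_since, psince)
    }
  }
  data.frame(time = as.POSIXct(acc$time, origin = "1970-01-01", tz = "UTC"),
             present = rep(TRUE, length(acc$time)),
             room = acc$room, posture = acc$posture,
             interacting_object = acc$interacting_object,
             emotion = acc$emotion, weather = acc$weather,
             speech_request = acc$speech_request,
             room_since = as.POSIXct(acc$room_since, origin = "1970-01-01",
                                     tz = "UTC"),
             posture_since = as.POSIXct(acc$posture_since,
                                        origin = "1970-01-01", tz = "UTC"),
             stringsAsFactors = FALSE)
}

tick_states <- function(row) {
  p <- participant_state(present = row$present, room = row$room,
                         posture = row$posture,
                         interacting_object = row$interacting_object,
                         emotion = row$emotion,
                         timestamp = row$time, room_since = row$room_since,
                         posture_since = row$posture_since)
  e <- environment_state(weather = row$weather, timestamp = row$time)
  list(p = p, e = e)
}

# Numeric view of a feature vector for the ground-truth logistic.
truth_term <- function(name, x) {
  if (grepl("=", name, fixed = TRUE)) {
    parts <- strsplit(name, "=", fixed = TRUE)[[1]]
    return(as.numeric(identical(unname(x[parts[1]]), parts[2])))
  }
  switch(name,
         hour = as.numeric(x[["hour_of_day"]]) - 12,
         day_of_week = as.numeric(x[["day_of_week"]]),
         rejections_today = min(3, suppressWarnings(
           as.numeric(x[["rejections_today"]])), na.rm = TRUE),
         0)
}

#' Ground-truth acceptance probability
#'
#' @param cfg a [sim_participant_config()].
#' @param x a [extract_features()] vector.
#' @param accepted_today interventions already accepted today (fatigue).
#' @return probability in `[0, 1]`.
#' @export
true_accept_prob <- function(cfg, x, accepted_today = 0L) {
  z <- stats::qlogis(cfg$accept_base_rate)
  for (nm in names(cfg$accept_weights))
    z <- z + cfg$accept_weights[[nm]] * truth_term(nm, x)
  p <- stats::plogis(z)
  max(0, min(1, p - cfg$fatigue_decrement * accepted_today))
}

#' Draw the participant's reaction to a delivery
#'
#' A Bernoulli accept draw from the ground-truth logistic (minus fatigue);
#' among accepts, the participant may still abandon by leaving the room
#' with probability `leave_prob`. Consumes the current RNG stream.
#'
#' @param cfg a [sim_participant_config()].
#' @param x the delivery-time [extract_features()] vector.
#' @param accepted_today interventions already accepted today.
#' @return list with `outcome` ("completed", "declined" or "left_room") and
#'   `score` (completed only, uniform 50-100).
#' @export
react_to_delivery <- function(cfg, x, accepted_today = 0L) {
  p <- true_accept_prob(cfg, x, accepted_today)
  if (stats::runif(1) < p) {
    if (stats::runif(1) < cfg$leave_prob)
      list(outcome = "left_room", score = NA_real_)
    else
      list(outcome = "completed", score = round(stats::runif(1, 50, 100)))
  } else {
    list(outcome = "declined", score = NA_real_)
  }
}

#' Run the full coach pipeline against a synthetic participant
#'
#' Closed loop over `days` simulated days: day planning at first detection
#' (agenda, then day insight), momentary planning on every 5-minute tick,
#' acceptance-model updates from every outcome, milestone detection after
#' completions, and the weekly coffee-session cadence. Randomness is split
#' into two sub-streams derived from `seed`: the participant state stream
#' and the coach-side reaction draws.
#'
#' @param plugins list of `goal_plugin`s; each is joined at its first
#'   difficulty level on `start_date`.
#' @param participant_cfg a [sim_participant_config()].
#' @param days number of simulated days.
#' @param seed integer master seed.
#' @param start_date first simulated day (default a Monday).
#' @param config a [coach_config()].
#' @return a `sim_trace`: `trace` (data.frame of decisions and actions),
#'   `log` (the event log), `state` (final `coach_state`) and `metrics`
#'   (`completed_per_goal`, `weekly_min_hit_rate`, `deliveries_per_day`,
#'   `veto_rate`).
#' @export
run_closed_loop <- function(plugins, participant_cfg, days, seed,
                            start_date = as.Date("2021-06-07"),
                            config = coach_config()) {
  start_date <- as.Date(start_date)
  participant_cfg$seed <- seed
  stream <- simulate_participant(participant_cfg, days, start_date)
  set.seed(seed + 1000003L)

  goals <- lapply(plugins, function(pl)
    instantiate_goal(pl, pl$difficulty_levels[[1]]$level_name, start_date))
  state <- coach_state(goals, config)

  trace <- list()
  note <- function(time, action, tool = NA_character_,
                   goal = NA_character_, score = NA_real_,
                   detail = NA_character_, requested = FALSE,
                   n_alternatives = NA_integer_) {
    trace[[length(trace) + 1L]] <<- data.frame(
      time = time, action = action, tool = tool, goal = goal, score = score,
      detail = detail, requested = requested,
      n_alternatives = n_alternatives, stringsAsFactors = FALSE)
  }

  plan_tools <- function() unique(vapply(state$plan$items,
                                         function(it) it$tool_type, ""))
  accepted_today <- 0L
  current_date <- as.Date(NA)

  cols <- as.list(stream)  # column access is much cheaper than df rows
  for (i in seq_len(nrow(stream))) {
    row <- list(time = cols$time[i], present = TRUE, room = cols$room[i],
                posture = cols$posture[i],
                interacting_object = cols$interacting_object[i],
                emotion = cols$emotion[i], weather = cols$weather[i],
                speech_request = cols$speech_request[i],
                room_since = cols$room_since[i],
                posture_since = cols$posture_since[i])
    st <- tick_states(row)
    now <- row$time
    date <- clock_date(now)

    if (is.na(current_date) || date != current_date) {
      current_date <- date
      accepted_today <- 0L
    }

    # speech request: pick a concrete tool from today's plan (if any)
    requested_tool <- NULL
    if (!is.na(row$speech_request)) {
      tools <- if (!is.null(state$plan) &&
                   identical(state$plan$date, date)) plan_tools() else character()
      if (length(tools) > 0L)
        requested_tool <- sample(tools, 1L)
    }
    st$p$last_speech_command <- if (is.null(requested_tool)) NA_character_
      else paste("run", requested_tool)

    res <- on_participant_detected(state, st$p, st$e, now,
                                   requested_tool = requested_tool)
    state <- res$state
    for (a in res$actions)
      note(now, a$action, detail = a$detail)

    dec <- res$decision
    if (!is.null(dec)) {
      if (dec$action == "deliver") {
        delivery <- list(goal_instance_id = dec$item$goal_instance_id,
                         tool_type = dec$item$tool_type,
                         requested = isTRUE(dec$requested))
        reaction <- react_to_delivery(participant_cfg,
                                      dec$features, accepted_today)
        rec <- handle_outcome(delivery, reaction$outcome, now,
                              reaction$score)
        if (rec$accepted) accepted_today <- accepted_today + 1L
        out <- record_outcome(state, rec, dec$features, now)
        state <- out$state
        note(now, "deliver", dec$item$tool_type, dec$item$goal_instance_id,
             dec$score, reaction$outcome, requested = isTRUE(dec$requested),
             n_alternatives = length(dec$alt_tools))
        for (ms in out$milestones)
          note(now, "agenda_milestone", goal = ms$goal_instance_id,
               detail = ms$kind)
      } else {
        note(now, dec$action, dec$item$tool_type,
             dec$item$goal_instance_id, dec$score, dec$reason)
      }
    }
  }

  trace <- do.call(rbind, trace)
  metrics <- closed_loop_metrics(state, trace, days)
  structure(list(trace = trace, log = state$log, state = state,
                 metrics = metrics), class = "sim_trace")
}

closed_loop_metrics <- function(state, trace, days) {
  log <- state$log
  completed_per_goal <- vapply(state$goals, function(g)
    count_completed(log, g$instance_id, g$start_date, goal_end_date(g)),
    0L)
  names(completed_per_goal) <- vapply(state$goals, `[[`, "", "instance_id")

  hits <- 0L; cells <- 0L
  for (g in state$goals) {
    for (w in seq_len(g$level$duration_weeks)) {
      wk_start <- week_monday(g$start_date) + (w - 1L) * 7L
      wk_end <- wk_start + 6L
      if (wk_start > max(log$date, g$start_date)) next
      if (wk_end > g$start_date + days - 1L) next  # only fully simulated weeks
      ref_day <- max(wk_start, g$start_date)
      reqs <- goal_week_requirements(g, ref_day)
      wmin <- sum(vapply(reqs, function(r) r$min_count, 0L))
      done <- count_completed(log, g$instance_id, wk_start, wk_end)
      cells <- cells + 1L
      if (done >= wmin) hits <- hits + 1L
    }
  }
  delivered <- if (is.null(trace)) 0L else sum(trace$action == "deliver")
  vetoed <- if (is.null(trace)) 0L else sum(trace$action == "skip_ml_veto")
  list(completed_per_goal = completed_per_goal,
       weekly_min_hit_rate = if (cells == 0L) NA_real_ else hits / cells,
       deliveries_per_day = delivered / days,
       veto_rate = if (delivered + vetoed == 0L) 0
                   else vetoed / (delivered + vetoed))
}

#' @export
print.sim_trace <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Closed-loop trace: %d decision(s), %d delivered, %d logged outcome(s)\n",
              nrow(x$trace), sum(x$trace$action == "deliver"), nrow(x$log)))
  cat(sprintf("  weekly_min_hit_rate %.3f, deliveries/day %.2f, veto rate %.3f\n",
              m$weekly_min_hit_rate, m$deliveries_per_day, m$veto_rate))
  cat(sprintf("  completed per goal: %s\n",
              paste(sprintf("%s=%d", names(m$completed_per_goal),
                            m$completed_per_goal), collapse = ", ")))
  invisible(x)
}

#' Write a closed-loop trace as JSON lines
#'
#' @param trace a `sim_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_trace <- function(trace, path) {
  df <- trace$trace
  lines <- vapply(seq_len(nrow(df)), function(i) {
    rec <- as.list(df[i, ])
    rec$time <- format(rec$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                  digits = NA))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
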