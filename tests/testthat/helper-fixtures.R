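# Fixture builders used across the suite. Everything is constructed in
# code; the only on-disk fixture is the canonical fiber_intake.json that
# ships with the package.

fixture_plugin_path <- function() {
  system.file("extdata", "fiber_intake.json", package = "smartcoach")
}

# one-tool plugin with identical weeks, for planner arithmetic
simple_plugin <- function(min_count = 3, max_count = 7, weeks = 4,
                          tool = "quiz", id = "simple",
                          dimension = "cognitive", ...) {
  wk <- function() list(intervention_requirement(tool, min_count, max_count,
                                                 ...))
  goal_plugin(id, paste("Simple", id), dimension,
              difficulty_levels = list(
                difficulty_level("easy", weeks,
                                 replicate(weeks, wk(), simplify = FALSE))),
              awareness_tips = character(),
              fallback_messages = "Keep going!")
}

# two-tool plugin used by the closed-loop tests
two_tool_plugin <- function(weeks = 4, id = "duo") {
  wk <- function() list(
    intervention_requirement("quiz", 3, 6),
    intervention_requirement("physical_trainer", 2, 5,
                             time_window = time_window("09:00", "20:00")))
  goal_plugin(id, "Two-tool goal", "physical",
              difficulty_levels = list(
                difficulty_level("easy", weeks,
                                 replicate(weeks, wk(), simplify = FALSE))),
              awareness_tips = c("Tip one.", "Tip two."),
              fallback_messages = c("Fallback one.", "Fallback two."))
}

# a log with `n` completed interventions for `goal` spread over given dates
log_with_completions <- function(goal_id, dates, tool = "quiz",
                                 scores = NULL) {
  log <- empty_event_log()
  for (i in seq_along(dates)) {
    rec <- list(time = make_test_clock(dates[i], 600 + i),
                goal_instance_id = goal_id, tool_type = tool,
                outcome = "completed", reason = "completed",
                score = if (is.null(scores)) 80 else scores[i],
                requested = FALSE, accepted = TRUE)
    log <- log_append(log, rec)
  }
  log
}

make_test_clock <- function(date, minute) {
  as.POSIXct(as.POSIXlt(as.Date(date)), tz = "UTC") + minute * 60
}

present_state <- function(clock, room = "living_room", posture = "sitting",
                          object = NA_character_, emotion = "positive") {
  participant_state(present = TRUE, room = room, posture = posture,
                    interacting_object = object, emotion = emotion,
                    timestamp = clock)
}

sunny <- function(clock) environment_state("sunny", timestamp = clock)

# a random feature vector drawn from the declared vocabularies
random_feature_vector <- function(vocab = feature_vocabularies()) {
  x <- vapply(vocab, function(v) sample(v, 1L), "")
  structure(x, class = "feature_vector")
}

MONDAY <- as.Date("2021-06-07")  # anchors week arithmetic in tests
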