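test_that("accomplishment rate follows its two branches and handles 0/0", {
  expect_identical(accomplishment_rate(3, 6), 0.5)
  expect_identical(accomplishment_rate(6, 6), 1)
  expect_identical(accomplishment_rate(9, 6), 1)
  expect_identical(accomplishment_rate(0, 0), 1)
  expect_identical(accomplishment_rate(0, 4), 0)
  expect_error(accomplishment_rate(-1, 2))
})

test_that("priority ranking is the exact printed linear combination", {
  # only the unmet-minimum and not-previous terms active
  inp <- ranking_inputs(not_min_reached = TRUE, not_previous = TRUE,
                        remaining_time = 1, time_range = 1,
                        carried_out = 1, minimum_target = 1)
  expect_equal(priority_rank(inp), 0.8)

  # all terms at zero
  zero <- ranking_inputs(not_previous = FALSE)
  expect_equal(priority_rank(zero), 0)

  # every term maximal: brute-force sum of the weights as the oracle
  maximal <- ranking_inputs(participant_requested = TRUE,
                            not_min_reached = TRUE, not_previous = TRUE,
                            requires_condition = TRUE,
                            remaining_time = 0, time_range = 1,
                            carried_out = 0, minimum_target = 5)
  weight_sum <- sum(c(1.1, 0.6, 0.2, 0.1, 0.06, 0.04))
  expect_equal(priority_rank(maximal), weight_sum)
  expect_equal(priority_rank(maximal), 2.1)

  # fractional urgency and accomplishment terms
  frac <- ranking_inputs(not_previous = FALSE, remaining_time = 30,
                         time_range = 120, carried_out = 1,
                         minimum_target = 4)
  expect_equal(priority_rank(frac), 0.06 * (1 - 30 / 120) + 0.04 * (1 - 0.25))
})

test_that("priority ranking is monotone in each input", {
  base <- list(participant_requested = FALSE, not_min_reached = FALSE,
               not_previous = FALSE, requires_condition = FALSE,
               remaining_time = 0.5, time_range = 1,
               carried_out = 2, minimum_target = 5)
  score <- function(args) priority_rank(do.call(ranking_inputs, args))
  for (flag in c("participant_requested", "not_min_reached",
                 "not_previous", "requires_condition")) {
    up <- base; up[[flag]] <- TRUE
    expect_gt(score(up), score(base))
  }
  less_time <- base; less_time$remaining_time <- 0.2
  expect_gt(score(less_time), score(base))
  more_done <- base; more_done$carried_out <- 4
  expect_lt(score(more_done), score(base))
  expect_error(ranking_inputs(remaining_time = 2, time_range = 1))
})

eligible_fixture <- function() {
  pl <- two_tool_plugin()
  goal <- instantiate_goal(pl, "easy", MONDAY)
  plan <- generate_day_plan(list(goal), empty_event_log(), MONDAY)
  list(goal = goal, plan = plan)
}

test_that("eligibility filtering removes capped, out-of-window and untriggered items", {
  fx <- eligible_fixture()
  clock <- make_test_clock(MONDAY, 10 * 60)
  p <- present_state(clock); e <- sunny(clock)

  elig <- filter_eligible(fx$plan, p, e, clock, empty_event_log())
  expect_setequal(vapply(elig, `[[`, "", "tool_type"),
                  c("quiz", "physical_trainer"))

  # daily_max reached -> excluded
  dmax <- Filter(function(it) it$tool_type == "quiz", fx$plan$items)[[1]]$daily_max
  lg <- log_with_completions(fx$goal$instance_id, rep(MONDAY, dmax), "quiz")
  elig2 <- filter_eligible(fx$plan, p, e, clock, lg)
  expect_false("quiz" %in% vapply(elig2, `[[`, "", "tool_type"))

  # outside the 09:00-20:00 window the windowed tool drops out
  night <- make_test_clock(MONDAY, 21 * 60)
  elig3 <- filter_eligible(fx$plan, present_state(night), sunny(night),
                           night, empty_event_log())
  expect_identical(vapply(elig3, `[[`, "", "tool_type"), "quiz")

  # trigger condition: tool kept only while touching the fridge
  pl <- simple_plugin(trigger_condition = condition_expr(
    list(field = "interacting_object", value = "fridge")))
  goal <- instantiate_goal(pl, "easy", MONDAY)
  plan <- generate_day_plan(list(goal), empty_event_log(), MONDAY)
  expect_length(filter_eligible(plan, p, e, clock, empty_event_log()), 0L)
  p_fridge <- present_state(clock, object = "fridge")
  expect_length(filter_eligible(plan, p_fridge, e, clock,
                                empty_event_log()), 1L)
})

test_that("selection prefers unmet minima and avoids the previous tool", {
  fx <- eligible_fixture()
  clock <- make_test_clock(MONDAY, 10 * 60)
  p <- present_state(clock); e <- sunny(clock)
  elig <- filter_eligible(fx$plan, p, e, clock, empty_event_log())

  # quiz already at its daily minimum -> the trainer (still below) wins
  lg <- log_with_completions(fx$goal$instance_id, rep(MONDAY, 1), "quiz")
  elig_lg <- filter_eligible(fx$plan, p, e, clock, lg)
  sel <- select_intervention(elig_lg, clock, lg)
  expect_identical(sel$item$tool_type, "physical_trainer")
  expect_true(sel$inputs$not_min_reached)

  # previous tool loses to an otherwise comparable alternative
  sel_prev <- select_intervention(elig, clock, empty_event_log(),
                                  previous_tool = "physical_trainer")
  expect_identical(sel_prev$item$tool_type, "quiz")

  # a requested tool outranks everything
  sel_req <- select_intervention(elig, clock, empty_event_log(),
                                 requested_tool = "physical_trainer")
  expect_identical(sel_req$item$tool_type, "physical_trainer")
  expect_gte(sel_req$score, 1.1)

  expect_null(select_intervention(list(), clock, empty_event_log()))
})

test_that("exact ties break by fewer completions today then tool name", {
  pl <- goal_plugin("tie", "Tie", "cognitive",
                    difficulty_levels = list(difficulty_level("easy", 4,
                      replicate(4, list(
                        intervention_requirement("b_tool", 0, 5),
                        intervention_requirement("a_tool", 0, 5)),
                        simplify = FALSE))),
                    fallback_messages = "ok")
  goal <- instantiate_goal(pl, "easy", MONDAY)
  plan <- generate_day_plan(list(goal), empty_event_log(), MONDAY)
  clock <- make_test_clock(MONDAY, 10 * 60)
  p <- present_state(clock); e <- sunny(clock)
  elig <- filter_eligible(plan, p, e, clock, empty_event_log())

  sel <- select_intervention(elig, clock, empty_event_log())
  expect_identical(sel$item$tool_type, "a_tool")  # lexicographic

  lg <- log_with_completions(goal$instance_id, MONDAY, "a_tool")
  sel2 <- select_intervention(filter_eligible(plan, p, e, clock, lg),
                              clock, lg)
  expect_identical(sel2$item$tool_type, "b_tool")  # fewer completions today
})

test_that("the delivery gate honours requests, waits and the capped veto", {
  cfg <- coach_config()
  fx <- eligible_fixture()
  clock <- make_test_clock(MONDAY, 10 * 60)
  p <- present_state(clock); e <- sunny(clock)
  elig <- filter_eligible(fx$plan, p, e, clock, empty_event_log())

  # requested: delivered 1 minute after the previous intervention
  sel_req <- select_intervention(elig, clock, empty_event_log(),
                                 requested_tool = "quiz")
  dec <- should_deliver(sel_req, clock - 60, clock, cfg = cfg)
  expect_identical(dec$action, "deliver")
  expect_identical(dec$reason, "participant_requested")

  # unrequested score in the 15-min bracket: 10 minutes is too soon
  sel <- select_intervention(elig, clock, empty_event_log())
  expect_gte(sel$score, 0.6)
  dec_wait <- should_deliver(sel, clock - 10 * 60, clock, cfg = cfg)
  expect_identical(dec_wait$action, "wait")
  dec_go <- should_deliver(sel, clock - 16 * 60, clock, cfg = cfg)
  expect_identical(dec_go$action, "deliver")

  # lowest bracket waits 45 minutes
  sel_low <- list(item = elig[[1]], score = 0.3,
                  inputs = ranking_inputs(not_previous = TRUE))
  dec_low <- should_deliver(sel_low, clock - 30 * 60, clock, cfg = cfg)
  expect_identical(dec_low$action, "wait")
  dec_low2 <- should_deliver(sel_low, clock - 46 * 60, clock, cfg = cfg)
  expect_identical(dec_low2$action, "deliver")

  # warm model predicting reject vetoes, but never past the cap
  m <- acceptance_model(cfg)
  x <- random_feature_vector()
  for (i in 1:30) m <- update(m, x, FALSE)  # all-reject warm model
  expect_lt(predict(m, x), 0.5)
  dec_veto <- should_deliver(sel, clock - 60 * 60, clock, model = m,
                             features = x, consecutive_vetoes = 0L,
                             cfg = cfg)
  expect_identical(dec_veto$action, "skip_ml_veto")
  dec_capped <- should_deliver(sel, clock - 60 * 60, clock, model = m,
                               features = x,
                               consecutive_vetoes = cfg$max_vetoes,
                               cfg = cfg)
  expect_identical(dec_capped$action, "deliver")

  # a cold model never vetoes
  cold <- acceptance_model(cfg)
  dec_cold <- should_deliver(sel, clock - 60 * 60, clock, model = cold,
                             features = x, consecutive_vetoes = 0L,
                             cfg = cfg)
  expect_identical(dec_cold$action, "deliver")
})

test_that("outcomes map to records with leave-room counting as rejection", {
  delivery <- list(goal_instance_id = "g1", tool_type = "quiz",
                   requested = FALSE)
  t0 <- make_test_clock(MONDAY, 600)

  done <- handle_outcome(delivery, "completed", t0, score = 80)
  expect_identical(done$outcome, "completed")
  expect_identical(done$score, 80)
  expect_true(done$accepted)

  left <- handle_outcome(delivery, "left_room", t0)
  expect_identical(left$outcome, "rejected")
  expect_identical(left$reason, "left_room")
  expect_false(left$accepted)

  post <- handle_outcome(delivery, "postponed", t0)
  expect_identical(post$outcome, "rejected")
  expect_identical(post$reason, "postponed")

  # a rejected tool returns to the pending pool
  pl <- simple_plugin(min_count = 1, max_count = 2)
  goal <- instantiate_goal(pl, "easy", MONDAY)
  plan <- generate_day_plan(list(goal), empty_event_log(), MONDAY)
  log <- log_append(empty_event_log(),
                    handle_outcome(list(goal_instance_id = goal$instance_id,
                                        tool_type = "quiz",
                                        requested = FALSE),
                                   "left_room", t0))
  p <- present_state(t0); e <- sunny(t0)
  elig <- filter_eligible(plan, p, e, t0, log)
  expect_identical(vapply(elig, `[[`, "", "tool_type"), "quiz")
})
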