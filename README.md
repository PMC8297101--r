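# smartcoach

Decision core of a virtual health coach for older adults ageing in place.
Care plans arrive as **SMART goal plugins** — self-contained 4–8-week plans
in one of four dimensions (cognitive, physical, social, nutritional), each
week listing intervention tools with minimum/maximum counts, optional time
windows and symbolic trigger conditions. The engine schedules those
interventions on three timescales:

* **weekly** — a coffee session reviews performance, lets the participant
  join or drop goals, and previews next week;
* **daily** — the weekly targets are turned into per-day targets: Monday to
  Wednesday the remaining weekly maximum is distributed evenly,
  `daily_max = ceil(remaining_max / days_left)`; from Thursday onwards a
  participant who has not kept up with the pro-rated minimum
  (`completed >= weekly_min * elapsed_days / 7`) has the target lowered to
  the minimum, `daily_min = daily_max = ceil(remaining_min / days_left)`;
* **momentary** — on every sensed state change, launchable items (below
  their daily cap, inside their window, trigger satisfied) are ranked by

  ```
  priority = 1.1·requested + 0.6·(min not reached) + 0.2·(not previous tool)
           + 0.1·(requires condition) + 0.06·(1 − remaining/range)
           + 0.04·(1 − accomplishment rate)
  ```

  with `accomplishment rate = min(1, carried_out / minimum_target)`. The top
  item is delivered if enough time has passed since the last intervention
  (the wait shrinks as priority grows), unless a per-participant **online
  accept/reject classifier** — an incrementally trained logistic model over
  one-hot context features, with periodic mutual-information feature
  selection — predicts a rejection; that veto is capped at a configurable
  number of consecutive uses, and directly requested interventions bypass
  every gate.

A synthetic-participant simulator (presence blocks, room/posture
transitions, a two-state emotion Markov chain, weather, and ground-truth
logistic acceptance with known weights) closes the loop so policies can be
exercised and evaluated entirely at desk scale. Analytics produce the
coffee-session performance bars, day-agenda milestones, and the daily
insight message with a guaranteed fallback.

## Worked example

```r
library(smartcoach)
plugin <- load_goal_plugin(system.file("extdata", "fiber_intake.json",
                                       package = "smartcoach"))
goal <- instantiate_goal(plugin, "easy", as.Date("2021-06-07"))
generate_day_plan(list(goal), empty_event_log(), as.Date("2021-06-10"))
#> Day plan for 2021-06-10 (2 item(s))
#>   fiber_intake#2021-06-07/quiz: 1-1 today (week 0/4 done)
#>   fiber_intake#2021-06-07/recipe_recommender: 1-1 today (week 0/3 done) [10:00-19:00] (triggered)
```

It is Thursday and nothing has been completed, so both tools collapse to
the minimum-based target of one launch today; the recommender additionally
carries its 10:00–19:00 window and its touching-the-fridge trigger. Scoring
one candidate directly:

```r
priority_rank(ranking_inputs(not_min_reached = TRUE, not_previous = TRUE,
                             requires_condition = TRUE,
                             remaining_time = 60, time_range = 540,
                             carried_out = 0, minimum_target = 1))
#> [1] 0.9933333
```

(0.6 for the unmet minimum, 0.2 for not repeating, 0.1 for the trigger,
plus almost the full 0.06 urgency with an hour left, and the full 0.04
shortfall term.) A whole month against a synthetic participant:

```r
sim <- sim_participant_config(accept_base_rate = 0.7,
                              accept_weights = c(hour = -0.3))
run_closed_loop(list(plugin), sim, days = 28, seed = 7)
#> Closed-loop trace: 143 decision(s), 41 delivered, 41 logged outcome(s)
#>   weekly_min_hit_rate 1.000, deliveries/day 1.46, veto rate 0.000
#>   completed per goal: fiber_intake#2021-06-07=28
```

Every weekly minimum was met (`weekly_min_hit_rate 1.0`) with about 1.5
deliveries per day; 28 interventions were completed towards the goal over
the four simulated weeks.

A thin command-line front end (`inst/cli/smartcoach.R`) wraps plugin
validation (`validate`, exit 0/1 with one `CODE path message` line per
violation), day-plan printing (`plan`) and closed-loop simulation
(`simulate`). The plugin file format is documented by the JSON-Schema in
`inst/extdata/goal-plugin.schema.json`.

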