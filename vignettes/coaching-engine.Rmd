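---
title: "The smartcoach decision engine: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The smartcoach decision engine: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartcoach)
```

smartcoach implements the decision core of a home virtual coach: it takes
expert-authored SMART goal plans, adapts them to what the participant
actually manages to do, and decides — event by event — whether this is a
good moment to offer an intervention. This vignette explains the model at
each timescale, the tunable parameters and their defaults, what the
synthetic participant does and does not emulate, and the choices made where
the design was genuinely open.

## Goal plans and week anchoring

A goal plugin carries one weekly plan per difficulty level: for each week,
a list of (tool, weekly minimum, weekly maximum) requirements, optionally
restricted to a within-day time window (half-open, local wall clock, never
crossing midnight) and/or to a symbolic trigger condition such as *touching
the fridge* or *sitting for at least 30 minutes*. Plan durations are 4–8
weeks; validation (`validate_goal_plugin()`) reports every violated
invariant with a machine-readable code and a field path, and never throws.

Goal weeks are calendar weeks starting Monday. This is forced by the daily
planner's Thursday rule (below), which needs an unambiguous notion of
"first half of the week" for every instance. A goal joined mid-week treats
the remainder of that calendar week as week 1, with its counts pro-rated by
`ceiling(count * remaining_days / 7)` — ceiling rather than rounding so a
short first week never silently drops a requirement to zero when the plan
asked for at least one.

Joining requirements ("not having Crohn's disease") are display-only text,
surfaced when a goal is joined during a coffee session. There is no
machine-readable health-condition model, so the engine deliberately never
evaluates them.

## The daily planner

Each day, per active goal and tool, with `completed` counting this
goal-week's completed interventions before today and `days_left` the days
remaining in the week including today:

* **Monday–Wednesday** (and any later day while the participant is on
  track): `daily_max = ceiling((weekly_max - completed) / days_left)`,
  `daily_min = ceiling((weekly_min - completed) / days_left)` — an even
  push towards the weekly maximum.
* **Thursday onwards, behind plan**: both bounds collapse to
  `ceiling((weekly_min - completed) / days_left)` — the target is lowered
  towards the minimum to keep the week achievable and the participant
  motivated.

"On track" is `completed >= weekly_min * elapsed_days / 7`: the pro-rated
minimum through yesterday. The rule needed a threshold and the pro-rated
minimum is the least surprising reading of "keeping up with the plan"; a
vacuous minimum (`weekly_min = 0`) is always on track. Remaining counts
never go negative, and items with no remaining daily capacity are omitted
from the plan — downstream filtering would drop them anyway, and small
plans are easier to audit.

Two subtleties worth noting. First, bounds are frozen when the plan is
generated; within the day only the *remaining capacity* (bound minus
completions) changes. Second, the daily maximum regenerated on a later day
is not globally monotone in completions: an extra completion can flip the
participant back to on-track, restoring the larger maximum-based target.
That is a direct consequence of the Thursday rule, not an accident, and the
tests assert monotonicity in the two regimes where it genuinely holds
(intra-day capacity; the Monday–Wednesday phase).

## Momentary planning

On every state change the day plan is filtered to items whose completions
today are below `daily_max`, whose window contains the clock, and whose
trigger condition holds. Eligible items are ranked by the fixed linear
heuristic

```
1.1·requested + 0.6·(minimum not reached) + 0.2·(not the previous tool)
+ 0.1·(requires condition) + 0.06·(1 − remaining/range)
+ 0.04·(1 − accomplishment rate)
```

with booleans coded 1/0 and `accomplishment rate` equal to 1 once the
minimum target is reached and `carried_out / minimum_target` before (a zero
minimum is vacuously met, avoiding 0/0). The weights are fixed constants of
the engine, originally set with domain experts; their ordering is the
behaviour: a direct speech request (1.1) outranks everything else combined
(max 1.0), unmet minima dominate variety, variety dominates the trigger
bonus, and the two fractional terms only break near-ties. Items without an
explicit window use the remainder of the day as their launch window, which
gives naturally increasing urgency towards the evening.

Three decisions were open here. Ties are broken by fewer completions today,
then lexicographic tool name — determinism matters more than any particular
choice. Repeating the previously delivered tool is treated as a hard
user-friendly restriction whenever a different eligible tool exists (the
0.2 term alone cannot guarantee it: an unmet minimum out-weighs it by
0.6 − 0.2), with requests exempt. And a speech request for a tool outside
today's plan is honoured as an extra delivery that leaves the plan's
bounds untouched, so requests are always representable.

The delivery gate then applies, in order: requests deliver immediately; a
wait bracket keyed on the priority score must have elapsed since the last
delivery (defaults: score ≥ 1.1 → no wait, ≥ 0.6 → 15 min, below → 45 min
— configuration, not behaviour; the engine is simply more insistent for
higher priorities); and a *warm* acceptance model predicting rejection may
postpone the delivery, at most `max_vetoes = 3` consecutive times, so a
biased or pessimistic model can never silence the coach. An intervention
abandoned by leaving the room, declined, or postponed is logged as rejected
and returns to the pending pool; completions carry the tool's score on a
common 0–100 scale.

## The acceptance model

The per-participant learner is an online logistic regression over one-hot
encoded categorical context features: hour of day (24 levels), day of week,
binned minutes since the last delivery, room, posture, emotion, interacting
object, weather, tool type, binned rejection counts and the tool's last
outcome. Missing fields encode as explicit `unknown` codes. Each labelled
outcome triggers one SGD step (learning rate 0.05) — O(1) in history — and
is appended to a sample store. Every `selection_period = 50` new samples,
all features are re-ranked by the empirical mutual information between
their values and the accept/reject label over the store; the top
`top_k = 8` become the active subset, the weights are re-initialised and
the store replayed. Mutual information was chosen because the vector is
categorical-heavy and the score must be model-agnostic. Prediction uses the
selected features only, returns exactly 0.5 until `warm_threshold = 20`
outcomes have been seen (cold predictions are noise, and 0.5 also disables
the veto, whose threshold is 0.5), and the whole state round-trips through
a single JSON document. Training is deterministic given the outcome stream:
replaying the same labels reproduces the state bit for bit.

## The synthetic participant

The simulator emulates the *outputs* of the sensing stack as symbolic
state: per-weekday presence blocks (default 09:00–21:00), random room and
posture transitions with onset timestamps (so duration triggers are
exercisable), occasional object interactions, a two-state emotion Markov
chain (default transition rows 0.9/0.1 and 0.3/0.7, stationary 75%
positive), and daily weather. Acceptance behaviour is a logistic in
declared features with known weights around a base rate (default 0.7, a
realistic adherence level for engaged participants), minus a fatigue
decrement of 0.02 per intervention already accepted today, with a 5%
chance of abandoning an accepted intervention by leaving the room. The
clock advances in 5-minute ticks, which bounds runtime while still
exercising the "sitting for 30 minutes" class of condition.

It deliberately does not model sensor noise, speech-recognition errors,
vision failures, or any correlation between context and availability
beyond the presence blocks. Passing closed-loop tests therefore show that
the *decision logic* is correct and learnable against a stationary,
honestly-reporting participant — not that the coach would perform
identically on real, noisy, non-stationary sensing data.

Closed-loop runs derive two sub-seeds from the master seed — one for the
participant state stream, one for the coach-side reaction draws — so
metrics are bit-identical across re-runs. Each delivery is resolved at the
delivery tick (accept, decline, or leave mid-intervention) rather than
held open across ticks; the leave-room-means-rejected semantics is
implemented and tested at the outcome-handling level.

## Analytics and messaging

Weekly bars fill `completed / weekly_max` (clamped to 1) with the mean
score of the week's completions; daily bars use the day-plan maxima
re-derived from the log as it stood each morning. Milestones (daily
minimum/maximum, per goal and across all goals) fire at most once per kind,
goal and day, with the fired-key set threaded through the caller so
repeated checks are quiet. The day insight is total by a strict precedence:
goal-performance (yesterday strictly beat every prior day's mean score, or
the last 7 days beat the last 30 — means, the least-surprising reading of
"last week against the month"), then user-model (a tracked sensing series
whose 7-day mean exceeds its 30-day mean by at least 0.5 standard
deviations), then a round-robin awareness tip, then a fallback message from
the plugin's mandatory pool. Only positive comparisons ever become
messages — the optimism constraint is asserted in the tests. Finished goals
get a difficulty suggestion: *harder* at ≥ 80% of the summed weekly maxima,
*easier* below 50% of the summed minima, *same* between (both thresholds
configurable).

## Orchestration

The coffee session is cadence-based — due 7 days after the last one rather
than pinned to a weekday, since no day is named — and auto-launches
whenever no goals are active or on request. Its three steps are fixed:
per-goal review (skippable; goals can be dropped; finished goals are
completed with a suggestion), join (requirements displayed), next-week
preview. On the first detection each day the agenda is shown, then the day
insight, and only then does the momentary loop run; milestone crossings
re-display the agenda with a motivational message. Dropping a goal removes
its remaining items immediately at the next replan.

## Problem sizes and test design

The suite checks the planner against a brute-force oracle over the full
grid `weekly_min ≤ weekly_max ≤ 10`, all weekdays and completion counts;
closed-loop invariants over ten 28-day simulations; learner recovery of an
hour-of-day logistic acceptance pattern over twenty seeds (600 training
offers, 200 held-out, accuracy above 0.70 on average and above chance in
every seed, hour-of-day recovered by feature selection in at least 18
seeds); attainability of every weekly minimum by a fully available,
always-accepting participant; and totality of the insight generator over
1,000 randomized logs. These sizes give stable statistics for each claim
while keeping the whole suite comfortably fast on one CPU.

## Known limitations

* Per-tool minima/maxima are interpreted per intervention requirement, not
  aggregated per goal; plans wanting a shared budget across tools must
  express it in one requirement.
* Postponed and declined interventions are both labelled *reject* for the
  learner; the data gives no way to distinguish "not now" from "not this".
* The wait brackets, veto cap, warm-up, feature-selection cadence and
  difficulty thresholds are defaults with face validity, not calibrated
  values; all live in `coach_config()`.
* The insight statistics use simple means and a pooled-SD trend test;
  seasonal or autocorrelated series can trigger or suppress user-model
  insights spuriously.
* The simulator's stationary acceptance process cannot exhibit concept
  drift, so the incremental learner's *adaptation* speed is only indirectly
  exercised (through feature-selection refits), not stress-tested.
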