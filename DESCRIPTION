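Package: smartcoach
Title: Adaptive Intervention Scheduling for SMART-Goal Virtual Coaching
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision core of a virtual health coach for older adults living
    at home. Coaching plans are SMART goal plugins (4-8 week care plans with
    weekly minimum/maximum intervention targets per tool); the engine turns
    them into daily targets with an even-distribution/Thursday-adjustment
    rule, selects the next intervention moment-by-moment with a priority
    ranking heuristic, and gates deliveries with an incremental accept/reject
    classifier with periodic feature selection. Includes goal-performance
    analytics (bars, milestones, day insights with guaranteed fallback), a
    weekly coffee-session orchestrator, and a synthetic-participant simulator
    for closed-loop evaluation without hardware or human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
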