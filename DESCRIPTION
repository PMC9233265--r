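Package: jitai
Title: Simulation and Evaluation of a Just-in-Time Adaptive Physical
    Activity Intervention Trial
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and evaluating within-subject wearable
    trials of just-in-time adaptive physical activity interventions in
    adolescents. Provides a minute-resolution synthetic trial generator
    with injectable prompt-response effects, the intervention's decision
    rules (adaptive daily goals, prompt framing tiers, reminders to move,
    consecutive-day voucher rewards, WHO sufficiency and eligibility
    screens), preprocessing to daily and weekly outcomes with the trial's
    exclusion rules, classic and bootstrapped paired one-tailed t tests
    for week-versus-baseline comparisons, and a change-point analysis of
    the physiological response to daily activity prompts (afternoon
    change-point detection, 30/60-minute pre/post effect magnitudes,
    weekly aggregation with a baseline control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
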