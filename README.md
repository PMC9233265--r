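# jitai

Simulation and evaluation machinery for within-subject wearable trials of
just-in-time adaptive physical-activity (PA) interventions in adolescents.

Minimalist smartphone + fitness-tracker interventions deliver personalized
activity prompts at moments of need (a *just-in-time adaptive intervention*,
JITAI) and are typically evaluated in small within-subject trials: a baseline
week followed by intervention weeks, each participant serving as their own
control. `jitai` re-implements that evaluation pipeline as tested, reusable
code for methodologists and intervention developers who want to exercise,
validate, or power such an analysis without access to participant data:

- a **synthetic trial generator** producing minute-resolution step and
  heart-rate (HR) records (18 participants × 4 seven-day periods by
  default) with diurnal activity structure, daily 5–7 PM prompts in
  intervention weeks, non-wear gaps, and *injectable* prompt-response
  effects whose ground truth is recorded for recovery scoring;
- the **intervention decision rules**: 5% adaptive weekly step/Active-Zone
  goals with hold on underperformance, five prompt-framing tiers
  (<40%, ≥40%, ≥60%, ≥80%, ≥100% of goal), template-based prompt rendering,
  reminders-to-move (4–9 PM, ≥250 steps), consecutive-day voucher rewards
  (3/5/7 days → €15/€30/€40), WHO sufficiency (≥60 MVPA min or ≥11,700
  steps/day) and PAQ-A eligibility screens;
- **preprocessing** to daily and weekly outcomes (MET-based sedentary and
  MVPA minutes, HR-based MVPA minutes, step count) with day-wise exclusion
  of >500-MVPA-minute outliers and ≤5-minute gap interpolation;
- **inference**: classic and bootstrapped paired one-tailed *t* tests of
  each intervention week against baseline, and a **change-point analysis**
  of the physiological response to the daily prompt.

## The statistics in brief

**Week vs baseline.** For each outcome and week, paired differences
`d_i = week_i − baseline_i` are oriented so the one-tailed alternative
(sedentary ↓, activity outcomes ↑) is positive; `t = mean(d)/(sd(d)/√n)`
with `df = n − 1` and upper-tail p. The bootstrap companion centers the
differences to the null (`d − mean(d)`), resamples them `B` times, and
reports `p = (1 + #{t* ≥ t_obs}) / (B + 1)`. Pairs missing a member are
dropped listwise per comparison; no multiplicity correction is applied.

**Prompt effect.** Per participant-day and signal (steps/min, HR), the
3–7 PM minute series is scanned by binary segmentation for changes in mean;
among candidates at or after 5 PM the *best-fitting* one — largest
single-split reduction in sum of squared errors over the window — is
selected. The effect magnitude is `mean(post L min) − mean(pre L min)` for
L = 30, 60. Magnitudes are averaged per participant and week and each
intervention week is tested against the baseline week, which undergoes the
identical procedure and thereby controls for random afternoon variation.

## Worked example

Simulate a trial in which prompts raise HR by 10 bpm for 60 minutes in week
2 only, and run the full analysis:

```r
library(jitai)

eff <- list(prompt_effect(), prompt_effect(),
            prompt_effect(delta_hr = 10, duration = 60), prompt_effect())
cfg <- sim_config(seed = 2024, prompt_effect_by_period = eff)
res <- run_pipeline(run_config(sim = cfg, seed = 7, n_boot = 10000))

res$effect_tests[res$effect_tests$signal == "heart_rate" &
                 res$effect_tests$window == 60,
                 c("period", "n", "df", "t", "p_classic", "p_bootstrap")]
#>   period  n df       t p_classic p_bootstrap
#> 1  week1 18 17  0.0203  4.92e-01      0.4875
#> 2  week2 18 17 10.4568  4.01e-09      0.0001
#> 3  week3 18 17  1.0228  1.60e-01      0.1465
```

Only the week-2 comparison — the week carrying the injected response — is
significant; its classic and bootstrap p values agree. The rendered
change-point table shows where that signal lives: pre/post-change HR means
per week and the mean per-minute increase (SD across participants):

```
Change-point analysis results
  Signal       Window  Period          Before        After  Increase/min (SD)
  heart_rate   60      baseline        95.019       95.072  0.05 (2.27)
  heart_rate   60      week1           94.773       94.841  0.07 (2.33)
  heart_rate   60      week2           94.878      103.016  8.14 (2.70)
  heart_rate   60      week3           94.226       95.197  0.97 (2.56)
```

The recovered week-2 increase (≈8 bpm) is the injected 10 bpm diluted by
change-point placement and afternoon noise; baseline and the uninjected
weeks sit near zero. `run_config(out_dir = ...)` additionally writes every
table, the exclusion/missingness logs and a manifest that makes the run
byte-for-byte reproducible.

The decision rules are plain functions:

```r
compute_reward(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))  # 30 (euros)
classify_prompt_tier(8450, 9900)$label                         # "GE80"
update_weekly_goal(goal_state(9000, 20), 10000)$step_goal      # 10500
```

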