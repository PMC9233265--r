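---
title: "Models and methods behind jitai"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind jitai}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jitai)
```

`jitai` packages the full evaluation machinery of a small within-subject
wearable trial of a just-in-time adaptive physical-activity intervention:
a synthetic minute-level data generator, the intervention's decision rules,
preprocessing to daily/weekly outcomes, paired one-tailed tests with a
bootstrap companion, and a change-point analysis of the response to daily
activity prompts. This vignette explains the underlying models, the
defaults and why they were chosen, and what the validation does and does
not establish.

## Trial design being emulated

Each of `n_participants` (default 18) adolescents wears an activity
tracker for four 7-day periods: a baseline week with no notifications,
then three intervention weeks. During intervention weeks each participant
receives one personalized activity prompt per day in the 5–7 PM window,
hourly reminders-to-move apply between 4 and 9 PM, weekly goals adapt to
the previous week's achievement, and consecutive goal-met days earn
voucher rewards. Every participant serves as their own control: each
intervention week is compared against the baseline week.

## The synthetic data generator

The generator's task is to produce data with the statistical structure the
analysis assumes — not to be a physiological model.

**Steps.** Minute step counts form an inhomogeneous count process. Each
minute of the day belongs to one of three latent states — sedentary, light
activity, or moderate-to-vigorous activity (MVPA) — drawn with
hour-modulated probabilities: the probability of being active in a minute
of hour *h* is proportional to a 24-hour weight profile (near zero
overnight, a morning rise, a broad daytime plateau, a late-afternoon
peak). Active minutes draw Poisson step counts at state-specific rates
(8.125 and 105 steps/min by default). Day-level activity scales with a
per-participant mean (normal, between-participant SD 4,500 steps) and
day-to-day noise (SD 2,500 steps).

**Heart rate.** HR is resting HR (normal across participants, mean 80
bpm, SD 7) plus an activity-coupled gain (+15 bpm in light minutes, +65 in
MVPA minutes) plus white noise (SD 3 bpm), rounded to integer bpm and
clipped to 30–220. There is deliberately no autocorrelated HR dynamics, no
recovery kinetics, and no heart-rate variability — the analysis under test
only uses minute-mean levels.

**Defaults.** 14,000 steps/day, 790 sedentary minutes/day and 90 MVPA
minutes/day at the population mean, resting HR 80 bpm: these place the
simulated daily summaries on the scale a real cohort of this kind reports,
so that test statistics and SDs live in realistic units. The
minute-intensity classification uses fixed step-rate cut-offs (≥60
steps/min moderate, ≥130 vigorous, 0 steps and HR < 100 bpm sedentary) as
a configurable stand-in for the tracker vendor's proprietary MET logic,
which is not public.

**Prompts and injectable effects.** One prompt per participant-day is
delivered at a minute drawn uniformly in the 17:00–19:00 window (the
design fixes only the interval, not a schedule; the draw is recorded in
the prompt log). A per-period *prompt effect* `(delta_hr, delta_steps,
onset_lag, duration)` raises HR deterministically and adds
Poisson-distributed steps for `duration` minutes from
`delivery + onset_lag`; the baseline period's effect is forced to zero
because no prompt exists there. All defaults are zero — the default trial
is a *null* trial — and every applied injection is stored in a
ground-truth table so recovery can be scored exactly. In the no-noise
limit the injected HR delta is recovered exactly (this is a test).

**Missingness.** Non-wear is modeled as contiguous gaps: a Poisson number
of gaps per day (mean 0.15) with mean length 40 minutes, placed uniformly;
gap minutes lose steps, HR and intensity together. This emulates forgotten
or removed devices. It does not emulate informative missingness (e.g.
removal *during* exercise), so missingness-robustness conclusions from
simulations are limited to missingness at random.

**What passing tests show.** Simulation-based tests establish that the
inference machinery is calibrated and recovers known signals *under this
generative model* — independent days, Gaussian/Poisson noise, mean-shift
responses. Real tracker data have autocorrelation, day-of-week structure
and behavioral feedback loops that the generator does not attempt; results
on real data inherit none of these guarantees.

## Intervention decision rules

- **Goals.** If last week's achieved daily average met or exceeded the
  goal, the new goal is `round(1.05 × achieved)`; otherwise the goal is
  held. "Underperformed" is read as *average below the previous goal*, and
  the 5% raise applies to the achieved average (not the old goal) — the
  literal reading of the rule as stated. Since a raise only happens when
  `achieved ≥ goal`, goals can never decrease. Goals round half-up;
  half-even banker's rounding would make goal sequences depend on parity
  artifacts.
- **Prompt tiers.** Five bands of percent-of-goal with inclusive lower
  bounds 0/40/60/80/100, partitioning `[0, ∞)`; the top band is unbounded.
- **Prompt rendering** fills five variables — name, steps so far, percent
  of goal (floored), a WHO-based health benefit, and the tier-keyed
  framing — from a packaged pool of 26 framing templates and 8 benefit
  sentences, drawn reproducibly under a seed.
- **Reminders.** Half-open window `[16, 21)`; an hour triggers only with
  zero steps *and* no HR-elevating activity; the target is 250 steps.
- **Rewards.** The longest run of consecutive goal-met days maps
  7→€40, 5–6→€30, 3–4→€15, else €0. Runs of 4 or 6 days pay the
  next-lower tier: the rule names only 3/5/7, and paying the largest
  attained tier is the only monotone completion. A "goal-met day" is
  judged on the step goal by default (whether both goals must be met is
  not specified; the choice is configurable at the call site by passing
  the appropriate flags).

## Preprocessing

Daily summaries count sedentary minutes and MET-MVPA minutes from the
minute intensity class, HR-MVPA minutes as wear minutes with HR at or
above a threshold (default 140 bpm ≈ 50% heart-rate reserve for a
17-year-old at resting HR 80 — the vendor's HR-zone metric is proprietary,
so the threshold is explicit and configurable), and the daily step total.
Days with more than 500 MET-MVPA minutes are excluded day-wise (the
exclusion is strict: 500 is retained; an implausible-device-artifact
rule). Days map to periods by `floor((date − start)/7)`. Weekly outcomes
are means over the *available* retained days rather than requiring 7/7 —
trials of this kind report results despite acknowledged missing data — and
a participant-period with no retained day stays missing so that paired
tests drop it listwise, shrinking the degrees of freedom mechanically.

## Paired tests

The classic test orients differences so the stated one-tailed alternative
is positive and uses the Student upper tail. Zero-variance differences
raise a typed degenerate-condition error rather than returning `t = ±Inf`;
inside the suites such comparisons are reported as *not computable*. The
bootstrap companion resamples **null-centered** differences and recomputes
*t* per resample; `p = (1 + #{t* ≥ t_obs})/(B + 1)` (add-one, so p is
never exactly 0), with `B = 10,000` by default. The centered differences
are sorted before resampling, which makes the bootstrap p exactly
invariant to participant order at no statistical cost. The resampling
scheme itself is a documented assumption — the analysis being emulated
names no scheme — and the percentile-t choice on centered differences is
the standard small-sample option. Significance is flagged at α = .05 on
the classic p, uncorrected: correction is deliberately not applied in this
design, a choice inherited here and confined to the significance flag.

## Change-point analysis of the prompt effect

Per participant-day and signal (steps, HR):

1. **Gap repair.** A day with more than 5 missing minutes in total is
   excluded; otherwise gaps are linearly interpolated between flanking
   values (nearest-value carry at the series boundary, logged). Whether
   the 5-minute tolerance is per gap or per day is ambiguous in the rule
   as stated; *total per day* is implemented, the stricter reading.
2. **Detection** on the 3–7 PM window (240 minutes): greedy binary
   segmentation for changes in mean — repeatedly split the segment whose
   best single split gives the largest reduction in within-segment sum of
   squared errors — up to `max_cp = 5` splits with `penalty = 0` (a split
   must improve the fit strictly; a constant window yields no candidate).
   The default is *not* an information-criterion gate on purpose: the
   procedure should return a best-fitting change point even on prompt-free
   days, because the baseline week is analyzed identically and absorbs
   noise-driven deltas. A stricter penalty and a different `max_cp` are
   configurable.
3. **Scoring and selection.** Every candidate is scored by the SSE
   reduction *a single split at that position achieves over the whole
   window*. Acceptance-stage gains are computed within sub-segments and
   are not comparable across recursion levels — concretely, the sharp
   *end* of a 60-minute response can outbid its onset on within-segment
   gain, flipping recovered deltas negative. With window-level scoring,
   the top candidate is exactly the exhaustive single-split scan (tested
   against an independent brute-force oracle), "best-fitting" has a single
   well-defined meaning, and ties resolve to the earliest minute. The
   best-scoring candidate at or after 5 PM is selected; a day with no such
   candidate contributes nothing and is logged, never imputed.
4. **Magnitude.** `mean(post) − mean(pre)` over half-open L-minute windows
   (L = 30, 60) drawn from the **full repaired day**, not just the
   detection frame: a 60-minute post-window from a 6:30 PM change point
   must extend past 7 PM. Windows truncate at the day boundary and require
   at least ⌈L/2⌉ observed minutes per side, else that L drops for the
   day.
5. **Aggregation and testing.** Magnitudes are averaged per participant ×
   period × signal × L; each intervention week is tested against the
   baseline week (one-tailed, increase) with the classic and bootstrap
   tests. The baseline control is the same procedure run on baseline days.

Validated properties (all in the test suite): exact localization of
noiseless shifts; localization within ±2 minutes in ≥90% of 1,000
simulations at signal-to-noise ratio 2; recovery of a +10 bpm/60-min
injected response with absolute bias < 0.5 bpm over 1,000 simulated days
at the default HR noise; agreement of the selected post-cutoff change
point with an exhaustive constrained SSE scan on 1,000 windows containing
a genuine post-cutoff shift. On pure-noise windows the greedy candidate
set need not contain the constrained global optimum — equivalence is a
property of the shift regime, not of arbitrary data.

## Numerical and degenerate-input choices

- Time is local clock time, minute-of-day 0–1439; all intervals are
  half-open `[start, end)`.
- Step counts are integers; HR is rounded to integer bpm and clipped to
  [30, 220], matching device output granularity.
- Tie-breaks: equal split gains → earliest minute; equal tier — not
  possible (bands partition).
- All-missing days summarize to zeros with an `all_missing` flag and are
  dropped before weekly aggregation; they never error.
- Every source of randomness is seeded; per-comparison bootstrap seeds are
  derived deterministically from the master seed, and pipeline reruns with
  the same configuration are byte-identical.

## Validation problem sizes

The test suite uses: 500 null trials at 8 participants for the type-I
checks (one a-priori cell per suite — rejections of different cells within
a trial share the baseline and are dependent, so a single-cell exact
binomial check at 99% bounds is the calibrated formulation); 100 trials at
the full 18 participants for week-2 effect recovery; 1,000 windows each
for detector-oracle equivalence, localization, and magnitude recovery; and
49,999 bootstrap resamples at n = 200 for bootstrap/classic agreement.
These sizes make the binomial and Monte-Carlo tolerances used in the tests
meaningful while keeping the default suite practical to run.

## Known limitations

- The generator's independence across days and participants understates
  the variance structure of real cohorts (holidays, weather, school
  schedules); power estimates from it are optimistic.
- HR-based MVPA depends on one explicit threshold; vendor zone metrics are
  more elaborate and not reproducible exactly.
- The change-point analysis handles one prompt per day; multiple within-day
  prompts would need multi-event attribution that is out of scope.
- Recovered effect magnitudes are diluted relative to the injected truth
  when the selected change point is offset from the response onset; the
  week-contrast tests are unaffected because baseline undergoes the same
  procedure.
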