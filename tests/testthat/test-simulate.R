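test_that("equal seeds give identical datasets, different seeds differ", {
  cfg <- small_config(seed = 42)
  tr1 <- simulate_trial(cfg)
  tr2 <- simulate_trial(cfg)
  expect_identical(tr1$minutes, tr2$minutes)
  expect_identical(tr1$prompts, tr2$prompts)
  expect_identical(tr1$injections, tr2$injections)
  tr3 <- simulate_trial(small_config(seed = 43))
  expect_false(identical(tr1$minutes$steps, tr3$minutes$steps))
})

test_that("trial structure matches the within-subject design", {
  cfg <- small_config(seed = 1)
  tr <- simulate_trial(cfg)
  expect_equal(nrow(tr$minutes), 4 * 28 * 1440)
  # one prompt per participant on every non-baseline day, none at baseline
  expect_equal(nrow(tr$prompts), 4 * 21)
  expect_true(all(tr$prompts$date >= cfg$start_date + 7))
  expect_true(all(tr$prompts$delivery_minute >= cfg$prompt_window[1] &
                    tr$prompts$delivery_minute < cfg$prompt_window[2]))
  expect_false(any(duplicated(tr$prompts[, c("participant_id", "date")])))
  # baseline effect forced to zero
  expect_equal(tr$effects$delta_hr[tr$effects$period == "baseline"], 0)
  expect_equal(tr$effects$delta_steps[tr$effects$period == "baseline"], 0)
})

test_that("minute records respect the domain invariants", {
  tr <- simulate_trial(small_config(seed = 5))
  m <- tr$minutes
  worn <- !is.na(m$steps)
  expect_true(all(m$steps[worn] >= 0))
  expect_true(all(m$heart_rate[worn] >= 30 & m$heart_rate[worn] <= 220))
  # intensity missing exactly when the minute is non-wear
  expect_identical(is.na(m$intensity), !worn)
  # per-day totals: minute steps sum to the daily summary (independent sum)
  daily <- summarize_days(m)
  by_day <- tapply(m$steps, paste(m$participant_id, m$date),
                   sum, na.rm = TRUE)
  expect_equal(as.vector(by_day[paste(daily$participant_id, daily$date)]),
               daily$step_count)
})

test_that("null-effect config leaves ground-truth deltas at zero", {
  cfg <- small_config(seed = 9, missing_gaps_per_day = 0)
  tr <- simulate_trial(cfg)
  expect_true(all(tr$injections$delta_hr == 0))
  expect_true(all(tr$injections$delta_steps == 0))
  expect_false(anyNA(tr$minutes$steps))
})

test_that("noise-free HR injection is recovered exactly around every prompt", {
  eff <- list(prompt_effect(), prompt_effect(delta_hr = 10, duration = 60))
  cfg <- sim_config(
    n_participants = 3L, n_periods = 2L, seed = 7,
    between_sd_hr = 0, hr_noise_sd = 0, hr_light_gain = 0, hr_mvpa_gain = 0,
    missing_gaps_per_day = 0, prompt_effect_by_period = eff
  )
  tr <- simulate_trial(cfg)
  key <- paste(tr$minutes$participant_id, tr$minutes$date)
  for (k in seq_len(nrow(tr$injections))) {
    inj <- tr$injections[k, ]
    hr <- tr$minutes$heart_rate[key == paste(inj$participant_id, inj$date)]
    post <- mean(hr[inj$onset_minute + 1:60])
    pre <- mean(hr[inj$onset_minute + (-60):(-1) + 1])
    expect_equal(post - pre, 10)
  }
})

test_that("injection changes only the effect window and clips bounds", {
  day <- make_day(steps = 0L, heart_rate = 80)
  out <- inject_prompt_response(day, 1030L, prompt_effect(delta_hr = 8,
                                                          duration = 30))
  changed <- out$heart_rate != day$heart_rate
  expect_equal(sum(changed), 30)
  expect_equal(which(changed), 1031:1060)
  expect_equal(unique(out$heart_rate[changed]), 88)
  expect_identical(out$steps, day$steps)

  # zero-magnitude effect leaves the day untouched
  same <- inject_prompt_response(day, 1030L, prompt_effect())
  expect_identical(same, day)

  # clipping at the physiological ceiling
  hot <- make_day(steps = 0L, heart_rate = 215)
  out2 <- inject_prompt_response(hot, 100L, prompt_effect(delta_hr = 20,
                                                          duration = 10))
  expect_equal(unique(out2$heart_rate[101:110]), 220)

  # windows extending past the end of the day are truncated, not an error
  out3 <- inject_prompt_response(day, 1400L, prompt_effect(delta_hr = 5,
                                                           duration = 120))
  expect_equal(sum(out3$heart_rate != day$heart_rate), 40)
})

test_that("mean added steps per minute matches the configured effect mean", {
  day <- make_day(steps = 0L, heart_rate = 80)
  eff <- prompt_effect(delta_steps = 12, duration = 30)
  set.seed(99)
  added <- replicate(1000, {
    out <- inject_prompt_response(day, 1020L, eff)
    sum(out$steps) / 30
  })
  se <- sd(added) / sqrt(length(added))
  expect_lt(abs(mean(added) - 12), 3 * se)
})

test_that("missingness matches its configured expectation and is contiguous", {
  tr <- simulate_trial(sim_config(n_participants = 36L, n_periods = 2L,
                                  seed = 2, missing_gaps_per_day = 0))
  set.seed(11)
  # expected 1 gap/day of mean length 5 -> 5 missing minutes/day
  out <- apply_missingness(tr$minutes, gaps_per_day = 1, gap_mean_length = 5)
  miss <- tapply(is.na(out$steps), paste(out$participant_id, out$date), sum)
  n_days <- length(miss)
  expect_equal(n_days, 36 * 14)
  se <- sd(miss) / sqrt(n_days)
  expect_lt(abs(mean(miss) - 5), 3 * se)
  # gap minutes lose all three signals together
  na_rows <- is.na(out$steps)
  expect_true(all(is.na(out$heart_rate[na_rows])))
  expect_true(all(is.na(out$intensity[na_rows])))
  # probability zero leaves the data untouched
  expect_identical(apply_missingness(tr$minutes, 0, 5), tr$minutes)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(n_periods = 1), "n_periods")
  expect_error(sim_config(between_sd_steps = -1), "between_sd_steps")
  expect_error(sim_config(diurnal_profile = rep(1, 24)), "diurnal_profile")
  expect_error(sim_config(diurnal_profile = rep(0.5, 10)), "diurnal_profile")
  expect_error(sim_config(prompt_window = c(1200, 1100)), "prompt_window")
  expect_error(sim_config(prompt_effect_by_period = list(prompt_effect())),
               "prompt_effect_by_period")
  expect_error(prompt_effect(duration = 0), "duration")
  # a non-zero baseline entry is overridden to zero
  eff <- list(prompt_effect(delta_hr = 5), prompt_effect(), prompt_effect(),
              prompt_effect())
  cfg <- sim_config(prompt_effect_by_period = eff)
  expect_equal(cfg$prompt_effect_by_period[[1]]$delta_hr, 0)
})
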