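test_that("gap repair interpolates small gaps and excludes large ones", {
  x <- rep(10, 100)
  expect_identical(repair_gaps(x)$values, x) # nothing to do

  x1 <- x
  x1[50] <- NA
  x1[49] <- 10
  x1[51] <- 20
  r <- repair_gaps(x1)
  expect_true(r$ok)
  expect_equal(r$values[50], 15) # linear midpoint
  expect_equal(r$n_missing, 1L)

  x6 <- x
  x6[10:15] <- NA # 6 missing > 5 allowed
  r6 <- repair_gaps(x6)
  expect_false(r6$ok)
  expect_match(r6$reason, "6 missing")

  x5 <- x
  x5[10:14] <- NA # exactly 5 is still repaired
  expect_true(repair_gaps(x5)$ok)

  # boundary gap: nearest-observed carry, flagged
  xb <- c(NA, NA, 4, 8, 12)
  rb <- repair_gaps(xb)
  expect_true(rb$ok)
  expect_true(rb$boundary_carry)
  expect_equal(rb$values, c(4, 4, 4, 8, 12))
})

test_that("a constant window yields no change-point candidates", {
  cands <- detect_change_points(rep(7, 240))
  expect_equal(nrow(cands), 0)
  expect_null(select_best_after_cutoff(cands))
})

test_that("a noiseless mean shift is localized exactly with its jump", {
  x <- c(rep(10, 150), rep(16, 90)) # shift at index 151
  cands <- detect_change_points(x, window_start = 900L)
  top <- cands[which.max(cands$gain), ]
  expect_equal(top$cp_minute, 900L + 150L)
  # the SSE reduction of the true split equals k(n-k)/n * jump^2
  expect_equal(top$gain, 150 * 90 / 240 * 36)
  day <- rep(10, 1440)
  day[(900 + 150 + 1):1440] <- 16
  mag <- effect_magnitude(day, 900L + 150L, 30)
  expect_equal(mag$delta, 6)
})

test_that("the top candidate equals the exhaustive single-split scan", {
  set.seed(101)
  for (i in 1:25) {
    x <- stats::rnorm(240) + c(rep(0, 120), rep(stats::runif(1, 1, 3), 120))
    cands <- detect_change_points(x, window_start = 0L)
    top <- cands$cp_minute[which.max(cands$gain)]
    expect_equal(top, oracle_best_split_minute(x, window_start = 0L))
  }
})

test_that("selection honors the 5 PM cutoff and breaks ties earliest", {
  # strong pre-cutoff shift, weak post-cutoff shift: post-cutoff wins
  x <- rep(0, 240)
  x[71:240] <- x[71:240] + 10  # minute 970: strong, before 5 PM
  x[181:240] <- x[181:240] + 2 # minute 1080: weak, after 5 PM
  cands <- detect_change_points(x, window_start = 900L)
  sel <- select_best_after_cutoff(cands, 1020L)
  expect_equal(sel$cp_minute, 1080L)

  # no candidate after the cutoff -> none
  y <- c(rep(0, 60), rep(5, 180))
  expect_null(select_best_after_cutoff(
    detect_change_points(y, window_start = 900L), 1020L
  ))

  # scan-level tie: in c(0, 4, 8) both splits reduce the SSE equally;
  # the earlier split must be taken
  cands_t <- detect_change_points(c(0, 4, 8), window_start = 0L)
  expect_equal(cands_t$cp_minute[which.max(cands_t$gain)], 1L)

  # selection-level tie on equal gains -> the earlier minute
  tie <- tibble::tibble(cp_minute = c(1050L, 1030L), gain = c(2, 2))
  expect_equal(select_best_after_cutoff(tie, 1020L)$cp_minute, 1030L)
})

test_that("effect magnitudes use half-open pre/post windows on the full day", {
  day <- rep(80, 1440)
  day[1101:1440] <- 90 # shift at minute 1100
  for (len in c(30, 60)) {
    mag <- effect_magnitude(day, 1100L, len)
    expect_equal(mag$pre_mean, 80)
    expect_equal(mag$post_mean, 90)
    expect_equal(mag$delta, 10)
  }
  # effect lasting 30 minutes diluted over a 60-minute window -> half
  day30 <- rep(80, 1440)
  day30[1101:1130] <- 90
  expect_equal(effect_magnitude(day30, 1100L, 30)$delta, 10)
  expect_equal(effect_magnitude(day30, 1100L, 60)$delta, 5)
  # constant series -> zero delta
  expect_equal(effect_magnitude(rep(6, 1440), 1100L, 60)$delta, 0)
  # a 60-minute window from a 6:30 PM change point leaves the detection
  # interval but stays within the day
  late <- effect_magnitude(rep(80, 1440), 1110L, 60)
  expect_equal(late$n_post, 60)
  # truncation at the day boundary below the minimum drops the window
  dropped <- effect_magnitude(rep(80, 1440), 1430L, 60)
  expect_false(dropped$ok)
  expect_match(dropped$reason, "insufficient")
})

test_that("noisy shifts are localized within 2 minutes at SNR 2", {
  set.seed(303)
  n_sim <- 1000
  hits <- 0L
  for (i in seq_len(n_sim)) {
    m <- sample(1025:1110, 1) # true change point, after the cutoff
    x <- stats::rnorm(240, 0, 1)
    idx <- (m - 900 + 1):240
    x[idx] <- x[idx] + 2 # SNR 2 at noise SD 1
    sel <- select_best_after_cutoff(
      detect_change_points(x, window_start = 900L), 1020L
    )
    if (!is.null(sel) && abs(sel$cp_minute - m) <= 2) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.9)
})

test_that("injected deltas are recovered with small bias at default noise", {
  set.seed(404)
  n_sim <- 1000
  deltas <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    day <- 80 + stats::rnorm(1440, 0, 3) # default minute HR noise
    m <- sample(1025:1080, 1)
    day[(m + 1):(m + 60)] <- day[(m + 1):(m + 60)] + 10
    sel <- select_best_after_cutoff(
      detect_change_points(day[901:1140], window_start = 900L), 1020L
    )
    deltas[i] <- if (is.null(sel)) NA else {
      effect_magnitude(day, sel$cp_minute, 60)$delta
    }
  }
  expect_lt(mean(is.na(deltas)), 0.05)
  expect_lt(abs(mean(deltas, na.rm = TRUE) - 10), 0.5)
})

test_that("per-day analysis excludes gappy days and logs non-contributors", {
  day <- make_day(steps = 2L, heart_rate = 80)
  day$steps[700:706] <- NA_integer_ # 7 missing minutes > 5
  day$heart_rate[700:706] <- NA_real_
  day$intensity[700:706] <- NA_character_
  res <- prompt_effects_by_day(day)
  expect_equal(nrow(res$effects), 0)
  expect_match(res$log$reason[1], "7 missing")

  # repaired day (5 missing) with a clean post-cutoff HR shift contributes
  day2 <- make_day(steps = 0L, heart_rate = 80)
  day2$heart_rate[1101:1200] <- 92
  day2$heart_rate[300:304] <- NA_real_
  day2$steps[300:304] <- NA_integer_
  day2$intensity[300:304] <- NA_character_
  res2 <- prompt_effects_by_day(day2, signals = "heart_rate")
  expect_equal(nrow(res2$effects), 2) # windows 30 and 60
  expect_equal(unique(res2$effects$cp_minute), 1100L)
  expect_equal(res2$effects$delta[res2$effects$window == 30], 12)
})

test_that("weekly aggregation averages valid days per participant-period", {
  start <- as.Date("2021-06-07")
  eff <- tibble::tibble(
    participant_id = c("P01", "P01", "P02"),
    date = start + c(7, 8, 7), signal = "heart_rate",
    cp_minute = 1050L, gain = 1, window = 60L,
    pre_mean = c(80, 82, 78), post_mean = c(84, 90, 78),
    delta = c(4, 8, 0)
  )
  wk <- weekly_prompt_effect(eff, start)
  w1 <- wk[wk$period == "week1" & wk$participant_id == "P01", ]
  expect_equal(w1$mean_delta, 6) # {4, 8} -> 6
  expect_equal(w1$n_days, 2L)
  single <- wk[wk$period == "week1" & wk$participant_id == "P02", ]
  expect_equal(single$mean_delta, 0)
  # periods without valid days are missing, shrinking downstream df
  expect_true(is.na(wk$mean_delta[wk$period == "baseline" &
                                    wk$participant_id == "P01"]))
})

test_that("the baseline control runs the identical procedure on baseline days", {
  set.seed(66)
  cfg <- sim_config(n_participants = 3L, n_periods = 2L, seed = 17,
                    missing_gaps_per_day = 0)
  tr <- simulate_trial(cfg)
  ctrl <- baseline_control(tr$minutes, cfg$start_date,
                           signals = "heart_rate", window_lengths = 60L)
  expect_true(all(ctrl$period == "baseline"))
  expect_equal(sort(unique(ctrl$participant_id)),
               sprintf("P%02d", 1:3))
  # a baseline day with an incidental activity burst yields a positive delta
  burst <- make_day(steps = 0L, heart_rate = 80)
  burst$heart_rate[1081:1140] <- 100
  burst$intensity <- classify_intensity(burst$steps, burst$heart_rate)
  one <- baseline_control(burst, as.Date("2021-06-07"),
                          signals = "heart_rate", window_lengths = 30L)
  expect_gt(one$mean_delta[1], 0)
  expect_error(baseline_control(burst[0, ], as.Date("2021-06-07")),
               class = "jitai_cp_error")
})

test_that("prompt-effect tests compare weeks against baseline per signal", {
  start <- as.Date("2021-06-07")
  # two participants, deterministic deltas: week1 clearly above baseline
  eff <- tidyr::expand_grid(
    participant_id = c("P01", "P02", "P03"),
    date = start + c(0:6, 7:13)
  )
  eff$signal <- "heart_rate"
  eff$cp_minute <- 1050L
  eff$gain <- 1
  eff$window <- 60L
  base_delta <- c(P01 = 0.5, P02 = -0.5, P03 = 0.1)
  wk_delta <- c(P01 = 6.2, P02 = 5.1, P03 = 7.4)
  eff$delta <- ifelse(eff$date < start + 7,
                      base_delta[eff$participant_id],
                      wk_delta[eff$participant_id])
  eff$pre_mean <- 80
  eff$post_mean <- 80 + eff$delta
  wk <- weekly_prompt_effect(eff, start)
  res <- prompt_effect_tests(wk, n_boot = 999, seed = 4)
  r1 <- res[res$period == "week1", ]
  expect_equal(r1$n, 3L)
  expect_equal(r1$df, 2L)
  # hand-computed t: d = {5.7, 5.6, 7.3}, mean 6.2, sd 0.9539
  d <- unname(wk_delta - base_delta)
  expect_equal(r1$t, mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-10)
  expect_true(r1$significant)
})
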