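#' Default 24-hour activity weight profile
#'
#' Relative share of daily ambulatory activity assigned to each clock hour
#' (hour 0 = midnight). Near-zero overnight, a morning commute rise, a broad
#' daytime plateau and a late-afternoon peak around the 5-7 PM prompt window,
#' tapering through the evening. Weights sum to 1.
#'
#' @return Numeric vector of length 24 summing to 1.
#' @export
default_diurnal_profile <- function() {
  w <- c(
    0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, # 00-06: sleep
    4.0, 5.0, 5.0, 5.0, 5.0, 6.0,      # 07-12: morning + school
    5.0, 5.0, 6.0, 6.5, 7.0, 7.0,      # 13-18: afternoon, prompt window
    6.0, 5.0, 4.0, 2.0, 1.0            # 19-23: evening taper
  )
  w / sum(w)
}

#' Per-period prompt-response effect
#'
#' Describes the hypothesized physiological response to a daily activity
#' prompt: starting `onset_lag` minutes after delivery, heart rate is raised
#' by `delta_hr` bpm and the minute step rate by `delta_steps` steps/min for
#' `duration` minutes.
#'
#' @param delta_hr Heart-rate increase in bpm.
#' @param delta_steps Mean added steps per minute (Poisson-distributed draw
#'   per minute; 0 adds exactly nothing).
#' @param onset_lag Minutes between prompt delivery and response onset.
#' @param duration Response duration in minutes (>= 1 when any effect is
#'   non-zero).
#' @return A list of class `prompt_effect`.
#' @export
prompt_effect <- function(delta_hr = 0, delta_steps = 0, onset_lag = 0,
                          duration = 60) {
  if (duration < 1) stop_field("duration", "must be >= 1 minute")
  if (onset_lag < 0) stop_field("onset_lag", "must be >= 0")
  if (delta_steps < 0) stop_field("delta_steps", "must be >= 0")
  structure(
    list(delta_hr = delta_hr, delta_steps = delta_steps,
         onset_lag = as.integer(onset_lag), duration = as.integer(duration)),
    class = "prompt_effect"
  )
}

zero_effect <- function() prompt_effect(0, 0, 0, 60)

is_zero_effect <- function(e) e$delta_hr == 0 && e$delta_steps == 0

#' Simulation configuration for a synthetic wearable trial
#'
#' Defines the generative conditions of a within-subject activity-tracker
#' trial: a baseline week followed by intervention weeks, minute-resolution
#' step and heart-rate records with a diurnal activity profile, daily
#' afternoon prompts during intervention weeks, injectable prompt-response
#' effects, and contiguous non-wear gaps.
#'
#' Steps are generated as an inhomogeneous count process: each minute is
#' sedentary, light or MVPA with hour-modulated probabilities, and active
#' minutes draw Poisson step counts at state-specific rates. Heart rate is
#' resting HR plus an activity-coupled gain plus white noise, rounded to
#' integer bpm.
#'
#' @param n_participants Number of participants (default 18).
#' @param n_periods Number of 7-day periods including baseline (default 4).
#' @param seed Integer seed; equal seeds give identical datasets.
#' @param start_date First trial day (a Monday by default).
#' @param mean_daily_steps Population mean daily step count (default 14,000,
#'   the scale of the trial's weekly step means).
#' @param between_sd_steps,within_sd_steps Between-participant and day-to-day
#'   SDs of the daily step target.
#' @param resting_hr,between_sd_hr Population resting heart rate (bpm) and
#'   its between-participant SD.
#' @param hr_noise_sd Minute-level white-noise SD of heart rate (bpm).
#' @param diurnal_profile 24 non-negative hourly activity weights summing
#'   to 1.
#' @param sedentary_base Expected sedentary minutes per day at the mean step
#'   level (default 790).
#' @param mvpa_minutes Expected MVPA minutes per day at the mean step level
#'   (default 90).
#' @param light_step_rate,mvpa_step_rate Poisson step rates (steps/min) for
#'   light and MVPA minutes.
#' @param hr_light_gain,hr_mvpa_gain Heart-rate elevation (bpm) during light
#'   and MVPA minutes.
#' @param moderate_step_cutoff,vigorous_step_cutoff Steps/min cut-offs used
#'   to classify minute intensity (a configurable stand-in for the tracker's
#'   proprietary MET logic).
#' @param elevated_hr_cutoff Heart rate (bpm) above which a zero-step minute
#'   is not classified sedentary.
#' @param missing_gaps_per_day Expected number of non-wear gaps per
#'   participant-day (Poisson).
#' @param missing_gap_mean_length Mean gap length in minutes (1 plus a
#'   Poisson draw).
#' @param prompt_window Half-open clock-minute interval `[start, end)` in
#'   which the daily prompt is delivered (default 17:00-19:00).
#' @param prompt_effect_by_period List of [prompt_effect()] objects, one per
#'   period. The baseline entry is forced to zero effect. Default: no effect
#'   in any period.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 18L,
                       n_periods = 4L,
                       seed = 1L,
                       start_date = as.Date("2021-06-07"),
                       mean_daily_steps = 14000,
                       between_sd_steps = 4500,
                       within_sd_steps = 2500,
                       resting_hr = 80,
                       between_sd_hr = 7,
                       hr_noise_sd = 3,
                       diurnal_profile = default_diurnal_profile(),
                       sedentary_base = 790,
                       mvpa_minutes = 90,
                       light_step_rate = 8.125,
                       mvpa_step_rate = 105,
                       hr_light_gain = 15,
                       hr_mvpa_gain = 65,
                       moderate_step_cutoff = 60,
                       vigorous_step_cutoff = 130,
                       elevated_hr_cutoff = 100,
                       missing_gaps_per_day = 0.15,
                       missing_gap_mean_length = 40,
                       prompt_window = c(1020L, 1140L),
                       prompt_effect_by_period = NULL) {
  if (!is.numeric(n_participants) || n_participants < 1) {
    stop_field("n_participants", "must be a positive count")
  }
  if (!is.numeric(n_periods) || n_periods < 2) {
    stop_field("n_periods", "must be >= 2 (baseline plus interventions)")
  }
  sds <- c(between_sd_steps = between_sd_steps,
           within_sd_steps = within_sd_steps,
           between_sd_hr = between_sd_hr, hr_noise_sd = hr_noise_sd)
  for (nm in names(sds)) {
    if (!is.numeric(sds[[nm]]) || sds[[nm]] < 0) {
      stop_field(nm, "standard deviations must be >= 0")
    }
  }
  if (length(diurnal_profile) != 24 || any(diurnal_profile < 0)) {
    stop_field("diurnal_profile", "needs 24 non-negative hourly weights")
  }
  if (abs(sum(diurnal_profile) - 1) > 1e-8) {
    stop_field("diurnal_profile", "weights must sum to 1")
  }
  if (mean_daily_steps <= 0) stop_field("mean_daily_steps", "must be > 0")
  if (sedentary_base < 0 || sedentary_base > 1440) {
    stop_field("sedentary_base", "must be in [0, 1440] minutes")
  }
  if (mvpa_minutes < 0 || sedentary_base + mvpa_minutes > 1440) {
    stop_field("mvpa_minutes", "sedentary_base + mvpa_minutes must be <= 1440")
  }
  if (length(prompt_window) != 2 || prompt_window[1] >= prompt_window[2] ||
      prompt_window[1] < 0 || prompt_window[2] > 1440) {
    stop_field("prompt_window", "must be [start, end) within 0..1440")
  }
  if (missing_gaps_per_day < 0) {
    stop_field("missing_gaps_per_day", "must be >= 0")
  }
  if (missing_gap_mean_length < 1) {
    stop_field("missing_gap_mean_length", "must be >= 1 minute")
  }

  n_periods <- as.integer(n_periods)
  if (is.null(prompt_effect_by_period)) {
    prompt_effect_by_period <- replicate(n_periods, zero_effect(),
                                         simplify = FALSE)
  }
  if (length(prompt_effect_by_period) != n_periods) {
    stop_field("prompt_effect_by_period",
               sprintf("needs one entry per period (%d)", n_periods))
  }
  prompt_effect_by_period <- lapply(prompt_effect_by_period, function(e) {
    if (!inherits(e, "prompt_effect")) {
      stop_field("prompt_effect_by_period",
                 "entries must be prompt_effect() objects")
    }
    e
  })
  # The baseline week has no prompts, hence exactly zero effect.
  prompt_effect_by_period[[1]] <- zero_effect()

  structure(
    list(
      n_participants = as.integer(n_participants),
      n_periods = n_periods,
      seed = as.integer(seed),
      start_date = as.Date(start_date),
      mean_daily_steps = mean_daily_steps,
      between_sd_steps = between_sd_steps,
      within_sd_steps = within_sd_steps,
      resting_hr = resting_hr,
      between_sd_hr = between_sd_hr,
      hr_noise_sd = hr_noise_sd,
      diurnal_profile = diurnal_profile,
      sedentary_base = sedentary_base,
      mvpa_minutes = mvpa_minutes,
      light_step_rate = light_step_rate,
      mvpa_step_rate = mvpa_step_rate,
      hr_light_gain = hr_light_gain,
      hr_mvpa_gain = hr_mvpa_gain,
      moderate_step_cutoff = moderate_step_cutoff,
      vigorous_step_cutoff = vigorous_step_cutoff,
      elevated_hr_cutoff = elevated_hr_cutoff,
      missing_gaps_per_day = missing_gaps_per_day,
      missing_gap_mean_length = missing_gap_mean_length,
      prompt_window = as.integer(prompt_window),
      prompt_effect_by_period = prompt_effect_by_period
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d participants, %d x 7-day periods, seed %d\n",
    x$n_participants, x$n_periods, x$seed
  ))
  cat(sprintf("  daily steps %s (between SD %s, within SD %s)\n",
              format(x$mean_daily_steps, big.mark = ","),
              x$between_sd_steps, x$within_sd_steps))
  cat(sprintf("  resting HR %g bpm (SD %g), minute noise SD %g\n",
              x$resting_hr, x$between_sd_hr, x$hr_noise_sd))
  cat(sprintf("  prompt window %02d:%02d-%02d:%02d\n",
              x$prompt_window[1] %/% 60, x$prompt_window[1] %% 60,
              x$prompt_window[2] %/% 60, x$prompt_window[2] %% 60))
  eff <- vapply(x$prompt_effect_by_period, function(e) {
    sprintf("(%+g bpm, %+g steps/min, lag %d, dur %d)",
            e$delta_hr, e$delta_steps, e$onset_lag, e$duration)
  }, character(1))
  cat("  effects: ", paste(eff, collapse = " "), "\n", sep = "")
  invisible(x)
}
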