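#' Classify minute intensity from steps and heart rate
#'
#' Fixed step-rate cut-offs stand in for the tracker's proprietary MET-based
#' minute classification: a minute with zero steps and no elevated heart rate
#' is sedentary; otherwise the steps/min rate decides light, moderate or
#' vigorous.
#'
#' @param steps Integer steps in the minute (NA for non-wear).
#' @param heart_rate Heart rate in bpm (NA allowed).
#' @param moderate_cutoff,vigorous_cutoff Steps/min thresholds.
#' @param elevated_hr_cutoff Zero-step minutes with HR at or above this are
#'   classified light rather than sedentary.
#' @return Character vector over `sedentary`, `light`, `moderate`,
#'   `vigorous`; NA where `steps` is NA (non-wear).
#' @export
classify_intensity <- function(steps, heart_rate = NA_real_,
                               moderate_cutoff = 60, vigorous_cutoff = 130,
                               elevated_hr_cutoff = 100) {
  elevated <- !is.na(heart_rate) & heart_rate >= elevated_hr_cutoff
  out <- rep(NA_character_, length(steps))
  obs <- !is.na(steps)
  out[obs] <- "light"
  out[which(obs & steps == 0 & !elevated)] <- "sedentary"
  out[which(steps >= moderate_cutoff)] <- "moderate"
  out[which(steps >= vigorous_cutoff)] <- "vigorous"
  out
}

# Shared injection core: raise HR deterministically, add Poisson steps.
# `idx` are row positions of the affected minutes inside `steps`/`hr`.
apply_effect_at <- function(steps, hr, idx, effect) {
  if (length(idx) == 0 || is_zero_effect(effect)) {
    return(list(steps = steps, hr = hr))
  }
  obs <- idx[!is.na(steps[idx])]
  if (effect$delta_steps > 0) {
    steps[obs] <- steps[obs] + rpois(length(obs), effect$delta_steps)
  }
  if (effect$delta_hr != 0) {
    hr[obs] <- clip(hr[obs] + effect$delta_hr, 30, 220)
  }
  steps[obs] <- pmax(steps[obs], 0L)
  list(steps = steps, hr = hr)
}

#' Inject a prompt-response effect into one participant-day
#'
#' Starting `onset_lag` minutes after `delivery_minute`, raises heart rate by
#' `delta_hr` bpm and adds a Poisson(`delta_steps`) step draw per minute for
#' `duration` minutes. Windows extending past minute 1439 are truncated.
#' Heart rate is re-clipped to the physiological 30-220 bpm range; non-wear
#' minutes are left missing.
#'
#' @param day A 1440-row minute tibble for one participant-day with columns
#'   `minute`, `steps`, `heart_rate` (and optionally `intensity`, which is
#'   re-derived when present).
#' @param delivery_minute Prompt delivery minute-of-day (0-1439).
#' @param effect A [prompt_effect()].
#' @param intensity_cutoffs Optional list with `moderate`, `vigorous`,
#'   `elevated_hr` used to re-derive the intensity column.
#' @return The modified day tibble.
#' @export
inject_prompt_response <- function(day, delivery_minute, effect,
                                   intensity_cutoffs = NULL) {
  stopifnot(inherits(effect, "prompt_effect"))
  if (delivery_minute < 0 || delivery_minute > 1439) {
    stop_field("delivery_minute", "must lie within the day (0-1439)")
  }
  from <- delivery_minute + effect$onset_lag
  to <- min(from + effect$duration - 1L, 1439L)  # truncate at end of day
  idx <- which(day$minute >= from & day$minute <= to)
  res <- apply_effect_at(day$steps, day$heart_rate, idx, effect)
  day$steps <- res$steps
  day$heart_rate <- res$hr
  if ("intensity" %in% names(day)) {
    cuts <- intensity_cutoffs %||%
      list(moderate = 60, vigorous = 130, elevated_hr = 100)
    day$intensity[idx] <- classify_intensity(
      day$steps[idx], day$heart_rate[idx],
      cuts$moderate, cuts$vigorous, cuts$elevated_hr
    )
  }
  day
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Insert contiguous non-wear gaps into minute records
#'
#' Emulates device removal and charging: per participant-day, a Poisson
#' number of gaps is drawn, each with length 1 plus a Poisson draw, placed
#' uniformly within the day. Gap minutes have steps, heart rate and intensity
#' all missing. Uses the current RNG state; seed upstream for
#' reproducibility.
#'
#' @param minutes Minute tibble (columns `participant_id`, `date`, `minute`,
#'   `steps`, `heart_rate`, `intensity`) sorted by participant, date, minute.
#' @param gaps_per_day Expected gaps per participant-day (Poisson mean).
#' @param gap_mean_length Mean gap length in minutes.
#' @return The minute tibble with gap minutes set to missing.
#' @export
apply_missingness <- function(minutes, gaps_per_day = 0.15,
                              gap_mean_length = 40) {
  if (gaps_per_day <= 0) {
    return(minutes)
  }
  days <- dplyr::distinct(minutes, .data$participant_id, .data$date)
  n_days <- nrow(days)
  n_gaps <- rpois(n_days, gaps_per_day)
  if (sum(n_gaps) == 0) {
    return(minutes)
  }
  day_of <- rep.int(seq_len(n_days), n_gaps)
  lens <- 1L + rpois(sum(n_gaps), gap_mean_length - 1)
  starts <- floor(runif(sum(n_gaps), 0, 1441 - lens))
  #

  # Minute rows are in fixed (participant, date, minute) order, so the rows
  # of day j occupy (j-1)*1440 + 1 .. j*1440.
  idx <- unlist(lapply(seq_along(day_of), function(g) {
    (day_of[g] - 1L) * 1440L + starts[g] + seq_len(lens[g])
  }), use.names = FALSE)
  idx <- unique(idx[idx <= nrow(minutes)])
  minutes$steps[idx] <- NA_integer_
  minutes$heart_rate[idx] <- NA_real_
  minutes$intensity[idx] <- NA_character_
  minutes
}

#' Simulate a complete within-subject wearable trial
#'
#' Generates minute-resolution step and heart-rate records for every
#' participant-day of the trial, delivers one prompt per participant on each
#' non-baseline day at a uniformly drawn minute inside the prompt window,
#' injects the configured per-period prompt-response effects, and finally
#' inserts non-wear gaps. The returned ground-truth tables make every
#' injected effect exactly recoverable.
#'
#' @param config A [sim_config()].
#' @return A list of class `jitai_trial` with elements
#'   \describe{
#'     \item{minutes}{tibble: participant_id, date, minute, steps,
#'       heart_rate, intensity (one row per participant-minute).}
#'     \item{prompts}{tibble: participant_id, date, delivery_minute (no
#'       baseline rows).}
#'     \item{effects}{tibble of the configured per-period effects (ground
#'       truth), baseline row all zero.}
#'     \item{injections}{tibble of every applied injection: participant_id,
#'       date, period, onset_minute, duration, delta_hr, delta_steps.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  p <- config
  n_p <- p$n_participants
  n_days <- 7L * p$n_periods
  pids <- sprintf("P%02d", seq_len(n_p))
  dates <- p$start_date + 0:(n_days - 1L)

  # participant-level draws
  mean_steps_i <- pmax(rnorm(n_p, p$mean_daily_steps, p$between_sd_steps),
                       1000)
  resting_i <- clip(rnorm(n_p, p$resting_hr, p$between_sd_hr), 50, 110)

  # participant-day grid (participant varies slowest, then date)
  grid <- tidyr::expand_grid(participant_id = pids, date = dates)
  n_pd <- nrow(grid)
  target <- pmax(rnorm(n_pd, rep(mean_steps_i, each = n_days),
                       p$within_sd_steps), 500)
  f <- target / p$mean_daily_steps  # day-level activity scale

  # minute-level state draws
  light_target <- 1440 - p$sedentary_base - p$mvpa_minutes
  active_target <- light_target + p$mvpa_minutes
  mvpa_frac <- p$mvpa_minutes / active_target
  w_min <- rep(p$diurnal_profile, each = 60) / 60  # per-minute hour weight

  minute <- rep(0:1439, times = n_pd)
  f_min <- rep(f, each = 1440L)
  p_active <- pmin(f_min * active_target * rep(w_min, times = n_pd), 0.98)
  n_min <- n_pd * 1440L
  active <- runif(n_min) < p_active
  mvpa <- active & (runif(n_min) < mvpa_frac)
  light <- active & !mvpa

  steps <- integer(n_min)
  steps[light] <- rpois(sum(light), p$light_step_rate)
  steps[mvpa] <- rpois(sum(mvpa), p$mvpa_step_rate)

  hr <- rep(rep(resting_i, each = n_days), each = 1440L) +
    p$hr_light_gain * light + p$hr_mvpa_gain * mvpa
  if (p$hr_noise_sd > 0) hr <- hr + rnorm(n_min, 0, p$hr_noise_sd)
  hr <- clip(round(hr), 30, 220)

  day_index <- as.integer(rep(grid$date - p$start_date, each = 1440L))

  # prompts: one per participant on every non-baseline day
  is_interv_day <- grid$date - p$start_date >= 7
  prompts <- grid[is_interv_day, ]
  prompts$delivery_minute <- p$prompt_window[1] +
    sample.int(diff(p$prompt_window), nrow(prompts), replace = TRUE) - 1L

  # injections (ground truth)
  prompt_period <- as.integer(prompts$date - p$start_date) %/% 7L + 1L
  injections <- tibble(
    participant_id = prompts$participant_id,
    date = prompts$date,
    period = period_of_day_index(as.integer(prompts$date - p$start_date),
                                 p$n_periods),
    delivery_minute = prompts$delivery_minute,
    onset_minute = NA_integer_, duration = NA_integer_,
    delta_hr = NA_real_, delta_steps = NA_real_
  )
  pd_row <- match(
    paste(prompts$participant_id, prompts$date),
    paste(grid$participant_id, grid$date)
  )
  for (k in seq_len(nrow(prompts))) {
    eff <- p$prompt_effect_by_period[[prompt_period[k]]]
    from <- prompts$delivery_minute[k] + eff$onset_lag
    to <- min(from + eff$duration - 1L, 1439L)
    injections$onset_minute[k] <- from
    injections$duration[k] <- to - from + 1L
    injections$delta_hr[k] <- eff$delta_hr
    injections$delta_steps[k] <- eff$delta_steps
    if (!is_zero_effect(eff) && from <= 1439L) {
      idx <- (pd_row[k] - 1L) * 1440L + (from:to) + 1L
      res <- apply_effect_at(steps, hr, idx, eff)
      steps <- res$steps
      hr <- res$hr
    }
  }

  intensity <- classify_intensity(steps, hr, p$moderate_step_cutoff,
                                  p$vigorous_step_cutoff,
                                  p$elevated_hr_cutoff)

  minutes <- tibble(
    participant_id = rep(grid$participant_id, each = 1440L),
    date = rep(grid$date, each = 1440L),
    minute = minute,
    steps = as.integer(steps),
    heart_rate = as.numeric(hr),
    intensity = intensity
  )

  minutes <- apply_missingness(minutes, p$missing_gaps_per_day,
                               p$missing_gap_mean_length)

  effects <- dplyr::bind_rows(lapply(seq_len(p$n_periods), function(i) {
    e <- p$prompt_effect_by_period[[i]]
    tibble(period = period_labels(p$n_periods)[i], period_index = i,
           delta_hr = e$delta_hr, delta_steps = e$delta_steps,
           onset_lag = e$onset_lag, duration = e$duration)
  }))

  structure(
    list(minutes = minutes, prompts = as_tibble(prompts), effects = effects,
         injections = injections, config = config),
    class = "jitai_trial"
  )
}

#' @export
print.jitai_trial <- function(x, ...) {
  cat(sprintf(
    "<jitai_trial> %d participants x %d days (%s minute rows), %d prompts\n",
    length(unique(x$minutes$participant_id)),
    length(unique(x$minutes$date)),
    format(nrow(x$minutes), big.mark = ","), nrow(x$prompts)
  ))
  nz <- x$effects[x$effects$delta_hr != 0 | x$effects$delta_steps != 0, ]
  if (nrow(nz) == 0) {
    cat("  no injected prompt effects (null trial)\n")
  } else {
    cat(sprintf("  injected effects in: %s\n",
                paste(nz$period, collapse = ", ")))
  }
  invisible(x)
}
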