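#' Repair short wear gaps by linear interpolation
#'
#' Days with at most `max_missing` missing minutes in total have each gap
#' linearly interpolated between the flanking observed values; gaps at the
#' series boundary are filled by carrying the nearest observed value. Days
#' with more missing minutes are excluded from the change-point analysis.
#'
#' @param x Numeric minute series (NA = missing).
#' @param max_missing Maximum total missing minutes tolerated per day
#'   (default 5; strictly more excludes the day).
#' @return List: `ok` (logical), `values` (repaired series or NULL),
#'   `n_missing`, `boundary_carry` (logical: a boundary gap was filled by
#'   nearest-value carry), `reason` (when excluded).
#' @export
repair_gaps <- function(x, max_missing = 5) {
  n_missing <- sum(is.na(x))
  if (n_missing > max_missing) {
    return(list(ok = FALSE, values = NULL, n_missing = n_missing,
                boundary_carry = FALSE,
                reason = sprintf("%d missing minutes > %g allowed",
                                 n_missing, max_missing)))
  }
  if (n_missing == 0) {
    return(list(ok = TRUE, values = x, n_missing = 0L,
                boundary_carry = FALSE, reason = NULL))
  }
  boundary <- is.na(x[1]) || is.na(x[length(x)])
  values <- zoo::na.approx(x, na.rm = FALSE, rule = 2)
  list(ok = TRUE, values = as.numeric(values), n_missing = n_missing,
       boundary_carry = boundary, reason = NULL)
}

# Best single mean-shift split of a segment: maximal reduction in total
# within-segment SSE. Returns the first index of the right segment (local,
# 2..n) and the gain; ties resolve to the earliest split.
best_split <- function(x) {
  n <- length(x)
  if (n < 2) return(NULL)
  cs <- cumsum(x)
  k <- seq_len(n - 1)
  mean_l <- cs[k] / k
  mean_r <- (cs[n] - cs[k]) / (n - k)
  gain <- k * (n - k) / n * (mean_l - mean_r)^2
  kb <- which.max(gain) # which.max takes the first maximum: earliest split
  list(right_start = kb + 1L, gain = gain[kb])
}

#' Detect mean-shift change points in an afternoon window
#'
#' Greedy binary segmentation for changes in mean: at each step the current
#' segment split giving the largest reduction in within-segment sum of
#' squared errors is accepted, and its two halves are re-scanned, until
#' `max_cp` change points are placed or no split improves the fit by more
#' than `penalty`. The first accepted candidate is therefore exactly the
#' exhaustive single-split scan over the whole window. A constant (or
#' no-change) window yields an empty candidate set: a split must reduce the
#' SSE strictly.
#'
#' The default penalty is 0 rather than an information-criterion gate: the
#' procedure is meant to return a best-fitting change point even on
#' prompt-free days, because the baseline week is analyzed identically and
#' controls for noise-driven deltas.
#'
#' @param values Gap-repaired minute series over the detection window.
#' @param window_start Minute-of-day of `values[1]` (default 900 = 3 PM).
#' @param max_cp Maximum number of change points to place (default 5).
#' @param penalty Minimal SSE reduction a split must exceed (strictly).
#' @return Tibble of candidates, ordered by minute: `cp_minute` (first
#'   minute of the post-change segment) and `gain` (SSE reduction at
#'   acceptance).
#' @export
detect_change_points <- function(values, window_start = 900L, max_cp = 5L,
                                 penalty = 0) {
  if (anyNA(values)) {
    abort("detection window contains missing values; repair gaps first",
          class = "jitai_cp_error")
  }
  n <- length(values)
  cand_idx <- integer(0)
  cand_gain <- numeric(0)
  # open segments [from, to] with their best split precomputed
  segs <- list()
  add_seg <- function(segs, from, to) {
    if (to > from) {
      sp <- best_split(values[from:to])
      if (!is.null(sp) && sp$gain > penalty) {
        segs[[length(segs) + 1L]] <- list(from = from, to = to,
                                          cp = from + sp$right_start - 1L,
                                          gain = sp$gain)
      }
    }
    segs
  }
  segs <- add_seg(segs, 1L, n)
  while (length(segs) > 0 && length(cand_idx) < max_cp) {
    gains <- vapply(segs, `[[`, numeric(1), "gain")
    best <- which.max(gains)
    seg <- segs[[best]]
    segs <- segs[-best]
    cand_idx <- c(cand_idx, seg$cp)
    cand_gain <- c(cand_gain, seg$gain)
    segs <- add_seg(segs, seg$from, seg$cp - 1L)
    segs <- add_seg(segs, seg$cp, seg$to)
  }
  # Score every candidate on a common scale: the SSE reduction a single
  # split at that position achieves over the whole window. Within-segment
  # acceptance gains are not comparable across recursion levels and would
  # let a sharp secondary shift (e.g. the end of a response) outbid its
  # onset.
  if (length(cand_idx) > 0) {
    cs <- cumsum(values)
    k <- cand_idx - 1L # left-segment length for a split starting at cand
    mean_l <- cs[k] / k
    mean_r <- (cs[n] - cs[k]) / (n - k)
    cand_gain <- k * (n - k) / n * (mean_l - mean_r)^2
  }
  ord <- order(cand_idx)
  tibble(cp_minute = window_start + cand_idx[ord] - 1L,
         gain = cand_gain[ord])
}

#' Select the best-fitting change point after the cutoff
#'
#' Among detected candidates at or after the selection cutoff (5 PM), the
#' one with the largest SSE reduction is chosen; equal fits resolve to the
#' earlier minute. Days with no qualifying candidate contribute nothing.
#'
#' @param candidates Candidate tibble from [detect_change_points()].
#' @param cutoff_minute Selection cutoff as minute-of-day (default 1020 =
#'   5 PM, inclusive).
#' @return A one-row tibble (`cp_minute`, `gain`) or `NULL`.
#' @export
select_best_after_cutoff <- function(candidates, cutoff_minute = 1020L) {
  ok <- candidates[candidates$cp_minute >= cutoff_minute, ]
  if (nrow(ok) == 0) return(NULL)
  ok <- ok[order(-ok$gain, ok$cp_minute), ]
  ok[1, ]
}

#' Pre/post effect magnitude around a change point
#'
#' Subtracts the mean of the `window_length` minutes before the change point
#' from the mean of the `window_length` minutes after it. Effect windows are
#' drawn from the full day's repaired series (they may extend beyond the
#' detection interval) and are truncated at the day boundary; a side with
#' fewer than `ceiling(window_length / 2)` observed minutes drops the day
#' for that window length.
#'
#' @param day_values Full-day (1440-minute) repaired series.
#' @param cp_minute Selected change-point minute-of-day.
#' @param window_length 30 or 60 minutes (any positive length accepted).
#' @return List with `ok = TRUE`, `pre_mean`, `post_mean`, `delta`
#'   (`post_mean - pre_mean`), `n_pre`, `n_post`; or `ok = FALSE` with a
#'   `reason` when a window has too few minutes.
#' @export
effect_magnitude <- function(day_values, cp_minute, window_length) {
  stopifnot(window_length >= 1)
  if (cp_minute < 1L || cp_minute > 1439L) {
    return(list(ok = FALSE,
                reason = "change point leaves no pre or post window"))
  }
  pre_min <- max(cp_minute - window_length, 0L)
  pre_idx <- seq(pre_min, cp_minute - 1L) + 1L
  post_max <- min(cp_minute + window_length - 1L, 1439L)
  post_idx <- seq(cp_minute, post_max) + 1L
  pre <- day_values[pre_idx]
  post <- day_values[post_idx]
  n_pre <- sum(!is.na(pre))
  n_post <- sum(!is.na(post))
  need <- ceiling(window_length / 2)
  if (n_pre < need || n_post < need) {
    return(list(ok = FALSE, reason = sprintf(
      "insufficient window data at cp %d (pre %d, post %d, need %d)",
      cp_minute, n_pre, n_post, need
    )))
  }
  pre_mean <- mean(pre, na.rm = TRUE)
  post_mean <- mean(post, na.rm = TRUE)
  list(ok = TRUE, pre_mean = pre_mean, post_mean = post_mean,
       delta = post_mean - pre_mean, n_pre = n_pre, n_post = n_post)
}

#' Per-day prompt-effect analysis
#'
#' Runs the full per-day change-point procedure on every participant-day:
#' day-level gap repair (days with more than `max_missing` missing minutes
#' are excluded), mean-shift detection on the 3-7 PM window, selection of
#' the best-fitting change point at or after 5 PM, and 30/60-minute pre/post
#' effect magnitudes — separately for the step and heart-rate signals.
#' Baseline days are analyzed identically even though no prompt was
#' delivered; they control for random afternoon variation.
#'
#' @param minutes Canonical minute tibble.
#' @param signals Signals to analyze (`"steps"`, `"heart_rate"`).
#' @param window_lengths Effect window lengths in minutes.
#' @param detect_start,detect_end Detection interval as minute-of-day,
#'   half-open (default 900-1140, i.e. 3-7 PM).
#' @param cutoff_minute Selection cutoff (default 1020 = 5 PM).
#' @param max_missing Per-day missing-minute tolerance for gap repair.
#' @param max_cp,penalty Detection settings passed to
#'   [detect_change_points()].
#' @return List: `effects` tibble (participant_id, date, signal, cp_minute,
#'   gain, window, pre_mean, post_mean, delta) and `log` tibble of excluded
#'   or non-contributing participant-days with reasons.
#' @export
prompt_effects_by_day <- function(minutes,
                                  signals = c("steps", "heart_rate"),
                                  window_lengths = c(30L, 60L),
                                  detect_start = 900L, detect_end = 1140L,
                                  cutoff_minute = 1020L, max_missing = 5,
                                  max_cp = 5L, penalty = 0) {
  minutes <- dplyr::arrange(minutes, .data$participant_id, .data$date,
                            .data$minute)
  n <- nrow(minutes)
  if (n == 0) {
    empty_eff <- tibble(
      participant_id = character(), date = as.Date(character()),
      signal = character(), cp_minute = integer(), gain = numeric(),
      window = integer(), pre_mean = numeric(), post_mean = numeric(),
      delta = numeric()
    )
    empty_log <- tibble(participant_id = character(),
                        date = as.Date(character()), signal = character(),
                        reason = character())
    return(list(effects = empty_eff, log = empty_log))
  }
  pid_all <- minutes$participant_id
  date_all <- minutes$date
  min_all <- minutes$minute
  new_day <- c(TRUE, pid_all[-1] != pid_all[-n] |
                 date_all[-1] != date_all[-n])
  starts <- which(new_day)
  ends <- c(starts[-1] - 1L, n)
  n_days <- length(starts)
  det_idx <- seq(detect_start, detect_end - 1L) + 1L

  # preallocated accumulators (one effect row per day x signal x window)
  cap <- n_days * length(signals) * length(window_lengths)
  e <- list(pid = character(cap), date = rep(date_all[1], cap),
            signal = character(cap), cp = integer(cap),
            gain = numeric(cap), window = integer(cap),
            pre = numeric(cap), post = numeric(cap), delta = numeric(cap))
  l <- list(pid = character(cap), date = rep(date_all[1], cap),
            signal = character(cap), reason = character(cap))
  ne <- 0L
  nl <- 0L
  add_log <- function(pid, day, sig, reason) {
    nl <<- nl + 1L
    l$pid[nl] <<- pid
    l$date[nl] <<- day
    l$signal[nl] <<- sig
    l$reason[nl] <<- reason
  }

  for (j in seq_len(n_days)) {
    rows <- starts[j]:ends[j]
    pid <- pid_all[starts[j]]
    day <- date_all[starts[j]]
    for (sig in signals) {
      x <- rep(NA_real_, 1440L)
      x[min_all[rows] + 1L] <- as.numeric(minutes[[sig]][rows])
      rep_day <- repair_gaps(x, max_missing)
      if (!rep_day$ok) {
        add_log(pid, day, sig, rep_day$reason)
        next
      }
      cands <- detect_change_points(rep_day$values[det_idx],
                                    window_start = detect_start,
                                    max_cp = max_cp, penalty = penalty)
      best <- select_best_after_cutoff(cands, cutoff_minute)
      if (is.null(best)) {
        add_log(pid, day, sig,
                sprintf("no change point at or after minute %d",
                        cutoff_minute))
        next
      }
      for (len in window_lengths) {
        mag <- effect_magnitude(rep_day$values, best$cp_minute, len)
        if (!mag$ok) {
          add_log(pid, day, sig, paste0("window ", len, ": ", mag$reason))
          next
        }
        ne <- ne + 1L
        e$pid[ne] <- pid
        e$date[ne] <- day
        e$signal[ne] <- sig
        e$cp[ne] <- best$cp_minute
        e$gain[ne] <- best$gain
        e$window[ne] <- as.integer(len)
        e$pre[ne] <- mag$pre_mean
        e$post[ne] <- mag$post_mean
        e$delta[ne] <- mag$delta
      }
    }
  }
  keep <- seq_len(ne)
  lkeep <- seq_len(nl)
  list(
    effects = tibble(
      participant_id = e$pid[keep], date = e$date[keep],
      signal = e$signal[keep], cp_minute = e$cp[keep],
      gain = e$gain[keep], window = e$window[keep],
      pre_mean = e$pre[keep], post_mean = e$post[keep],
      delta = e$delta[keep]
    ),
    log = tibble(
      participant_id = l$pid[lkeep], date = l$date[lkeep],
      signal = l$signal[lkeep], reason = l$reason[lkeep]
    )
  )
}

#' Weekly aggregation of prompt-effect magnitudes
#'
#' Per participant, period, signal and window length, the mean pre/post
#' means and the mean change-point delta over that participant's valid days
#' in the period. Participant-periods with no valid day stay missing, so the
#' paired tests drop them listwise (shrinking the degrees of freedom).
#'
#' @param day_effects `effects` tibble from [prompt_effects_by_day()].
#' @param trial_start First day of the baseline week.
#' @return Tibble: participant_id, period, signal, window, pre_mean,
#'   post_mean, mean_delta, n_days.
#' @export
weekly_prompt_effect <- function(day_effects, trial_start) {
  trial_start <- as.Date(trial_start)
  day_effects |>
    dplyr::mutate(period = period_of_day_index(
      as.integer(.data$date - trial_start)
    )) |>
    dplyr::group_by(.data$participant_id, .data$period, .data$signal,
                    .data$window) |>
    dplyr::summarise(
      pre_mean = mean(.data$pre_mean),
      post_mean = mean(.data$post_mean),
      mean_delta = mean(.data$delta),
      n_days = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(.data$participant_id, .data$period, .data$signal,
                    .data$window, fill = list(n_days = 0L)) |>
    dplyr::arrange(.data$participant_id, .data$period, .data$signal,
                   .data$window)
}

#' Baseline control for the prompt-effect analysis
#'
#' Runs the identical detect-select-magnitude-aggregate procedure on the
#' baseline week only. No prompt was delivered at baseline; the resulting
#' deltas measure random afternoon variation and serve as the comparison
#' value for the treatment weeks.
#'
#' @inheritParams prompt_effects_by_day
#' @param trial_start First day of the baseline week.
#' @return Weekly effect tibble (baseline rows only), as from
#'   [weekly_prompt_effect()].
#' @export
baseline_control <- function(minutes, trial_start, ...) {
  trial_start <- as.Date(trial_start)
  base <- minutes[minutes$date >= trial_start &
                    minutes$date < trial_start + 7, ]
  if (nrow(base) == 0) {
    abort("no baseline days found in the 7 days from trial_start",
          class = "jitai_cp_error")
  }
  per_day <- prompt_effects_by_day(base, ...)
  out <- weekly_prompt_effect(per_day$effects, trial_start)
  out[out$period == "baseline", ]
}

#' Paired tests of weekly prompt effects against baseline
#'
#' For each signal and window length, classic and bootstrapped paired
#' one-tailed t tests (alternative: increase) of each intervention week's
#' mean change-point delta against the baseline control, with listwise
#' deletion per comparison.
#'
#' @param weekly_effects Tibble from [weekly_prompt_effect()] including
#'   baseline rows.
#' @param n_boot,seed,alpha As in [week_vs_baseline_suite()].
#' @return Tibble: signal, window, period, n, df, t, p_classic,
#'   p_bootstrap, mean_diff, significant, note.
#' @export
prompt_effect_tests <- function(weekly_effects, n_boot = 10000L, seed = 1L,
                                alpha = 0.05) {
  periods <- setdiff(levels(factor(weekly_effects$period)), "baseline")
  combos <- dplyr::distinct(weekly_effects, .data$signal, .data$window)
  rows <- list()
  i <- 0L
  for (ci in seq_len(nrow(combos))) {
    sig <- combos$signal[ci]
    win <- combos$window[ci]
    sub <- weekly_effects[weekly_effects$signal == sig &
                            weekly_effects$window == win, ]
    base <- sub[sub$period == "baseline", ]
    for (per in periods) {
      i <- i + 1L
      wk <- sub[sub$period == per, ]
      m <- match(base$participant_id, wk$participant_id)
      b <- base$mean_delta
      w <- wk$mean_delta[m]
      res <- tryCatch(
        bootstrap_paired_t(b, w, "increase", n_boot, derive_seed(seed, i)),
        jitai_stats_error = function(e) NULL,
        jitai_degenerate_error = function(e) NULL
      )
      if (is.null(res)) {
        res <- tibble(n = sum(!is.na(b) & !is.na(w)), df = NA_integer_,
                      t = NA_real_, p_classic = NA_real_,
                      p_bootstrap = NA_real_, mean_diff = NA_real_,
                      n_boot = as.integer(n_boot), seed = NA_integer_)
        res$note <- "not computable"
      } else {
        res$note <- ""
      }
      res$signal <- sig
      res$window <- win
      res$period <- per
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p_classic) & out$p_classic < alpha
  out[, c("signal", "window", "period", "n", "df", "t", "p_classic",
          "p_bootstrap", "mean_diff", "significant", "note")]
}
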