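#' Daily outcome summaries from minute records
#'
#' Collapses minute records into the four trial outcomes per participant-day:
#' MET/intensity-based sedentary minutes, MET-based MVPA minutes
#' (moderate + vigorous), heart-rate-based MVPA minutes (wear minutes with HR
#' at or above the moderate threshold — a configurable stand-in for the
#' tracker's proprietary HR-zone metric) and total step count, plus wear
#' minutes. A fully missing day yields zeros, zero wear minutes and an
#' `all_missing` flag.
#'
#' @param minutes Canonical minute tibble.
#' @param hr_moderate_threshold Heart rate (bpm) at or above which a wear
#'   minute counts as HR-based MVPA. The default 140 approximates 50% of
#'   heart-rate reserve for a 17-year-old with a resting HR of 80.
#' @return Tibble with one row per participant-day: `participant_id`,
#'   `date`, `sedentary_minutes`, `met_mvpa_minutes`, `hr_mvpa_minutes`,
#'   `step_count`, `wear_minutes`, `all_missing`.
#' @export
summarize_days <- function(minutes, hr_moderate_threshold = 140) {
  minutes |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      sedentary_minutes = sum(.data$intensity == "sedentary", na.rm = TRUE),
      met_mvpa_minutes = sum(.data$intensity %in% c("moderate", "vigorous"),
                             na.rm = TRUE),
      hr_mvpa_minutes = sum(!is.na(.data$heart_rate) &
                              .data$heart_rate >= hr_moderate_threshold),
      step_count = sum(.data$steps, na.rm = TRUE),
      wear_minutes = sum(!is.na(.data$steps)),
      .groups = "drop"
    ) |>
    dplyr::mutate(all_missing = .data$wear_minutes == 0L)
}

#' Exclude outlier days by MET-MVPA minutes
#'
#' Days with strictly more than `mvpa_limit` MET-based MVPA minutes are
#' removed as implausible device artifacts (the trial's rule excluded days
#' with >500 MVPA minutes). Exclusion is day-wise: other days of the same
#' participant are kept.
#'
#' @param days Daily summary tibble from [summarize_days()].
#' @param mvpa_limit Strict upper limit (default 500 minutes).
#' @return List with `retained` and `excluded` tibbles (the latter carries a
#'   `reason` column).
#' @export
exclude_outlier_days <- function(days, mvpa_limit = 500) {
  out <- days$met_mvpa_minutes > mvpa_limit
  excluded <- days[out, ]
  if (nrow(excluded) > 0) {
    excluded$reason <- sprintf("met_mvpa_minutes %d > %g",
                               excluded$met_mvpa_minutes, mvpa_limit)
  } else {
    excluded$reason <- character(0)
  }
  list(retained = days[!out, ], excluded = excluded)
}

#' Tag days with their trial period
#'
#' Day `d` belongs to period `floor((d - start)/7)`: baseline, week1, week2
#' or week3. Days outside the 28-day trial window are dropped and returned
#' in the `rejected` attribute.
#'
#' @param days Daily summary tibble with a `date` column.
#' @param trial_start First day of the baseline week.
#' @return The input tibble with a `period` factor column added, days
#'   outside the trial removed; attribute `rejected` holds the dropped rows.
#' @export
assign_periods <- function(days, trial_start) {
  trial_start <- as.Date(trial_start)
  offset <- as.integer(days$date - trial_start)
  in_range <- offset >= 0L & offset < 28L
  tagged <- days[in_range, ]
  tagged$period <- period_of_day_index(offset[in_range])
  attr(tagged, "rejected") <- days[!in_range, ]
  tagged
}

#' Aggregate daily outcomes into weekly records
#'
#' Per participant and period, the arithmetic mean of each outcome over the
#' retained days (up to 7). Participant-periods with no retained day are
#' kept as missing rows so that downstream paired tests drop them listwise.
#'
#' @param tagged_days Output of [assign_periods()] (after outlier
#'   exclusion).
#' @return Tibble with one row per participant-period: the four outcome
#'   means and `n_days` contributing.
#' @export
aggregate_weekly <- function(tagged_days) {
  tagged_days |>
    dplyr::group_by(.data$participant_id, .data$period) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(OUTCOME_COLUMNS), mean),
      n_days = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(.data$participant_id, .data$period,
                    fill = list(n_days = 0L)) |>
    dplyr::arrange(.data$participant_id, .data$period)
}

#' Wear-gap and missing-data report
#'
#' Lists per-day missing-minute totals and flags participants with any
#' contiguous non-wear gap longer than 24 hours (the trial's follow-up-email
#' trigger).
#'
#' @param minutes Canonical minute tibble.
#' @param flag_hours Gap length in hours above which a participant is
#'   flagged (default 24; strictly greater).
#' @return List with `daily_missing` (participant_id, date,
#'   missing_minutes) and `flagged` (participant_id, longest_gap_minutes for
#'   participants whose longest gap exceeds the threshold).
#' @export
missingness_report <- function(minutes, flag_hours = 24) {
  daily <- minutes |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(missing_minutes = sum(is.na(.data$steps)),
                     .groups = "drop")

  longest_gap <- function(is_missing) {
    r <- rle(is_missing)
    max(c(0L, r$lengths[r$values]))
  }
  gaps <- minutes |>
    dplyr::arrange(.data$participant_id, .data$date, .data$minute) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(longest_gap_minutes = longest_gap(is.na(.data$steps)),
                     .groups = "drop")
  flagged <- gaps[gaps$longest_gap_minutes > flag_hours * 60, ]
  list(daily_missing = daily, flagged = flagged)
}
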