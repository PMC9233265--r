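#' Pipeline run configuration
#'
#' Declares one reproducible simulate-preprocess-analyze run: either a
#' simulation configuration or an input dataset directory, the analysis
#' thresholds, bootstrap settings and the output directory. The seed is
#' recorded in every output.
#'
#' @param sim A [sim_config()] (used when `input_dir` is NULL).
#' @param input_dir Optional directory with a canonical dataset (see
#'   [read_canonical_csv()]); `trial_start` must then be supplied.
#' @param trial_start First baseline day; defaults to the simulation start
#'   date.
#' @param seed Integer master seed for the analysis (bootstraps).
#' @param n_boot Bootstrap resamples per test.
#' @param hr_moderate_threshold HR-MVPA threshold in bpm.
#' @param mvpa_outlier_limit Day-wise MET-MVPA exclusion limit (strict).
#' @param max_missing Per-day missing-minute tolerance for gap repair.
#' @param window_lengths Effect window lengths in minutes.
#' @param alpha Significance level.
#' @param out_dir Output directory for the report bundle (NULL = do not
#'   write files).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       trial_start = NULL, seed = 1L, n_boot = 10000L,
                       hr_moderate_threshold = 140,
                       mvpa_outlier_limit = 500, max_missing = 5,
                       window_lengths = c(30L, 60L), alpha = 0.05,
                       out_dir = NULL) {
  for (nm in c("n_boot", "hr_moderate_threshold", "mvpa_outlier_limit",
               "max_missing", "alpha")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0) stop_field(nm, "must be positive")
  }
  if (is.null(trial_start)) {
    trial_start <- if (is.null(input_dir)) sim$start_date else NULL
  }
  if (is.null(trial_start)) {
    stop_field("trial_start", "required when reading an input dataset")
  }
  structure(
    list(sim = sim, input_dir = input_dir,
         trial_start = as.Date(trial_start), seed = as.integer(seed),
         n_boot = as.integer(n_boot),
         hr_moderate_threshold = hr_moderate_threshold,
         mvpa_outlier_limit = mvpa_outlier_limit,
         max_missing = max_missing,
         window_lengths = as.integer(window_lengths), alpha = alpha,
         out_dir = out_dir),
    class = "run_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)),
          class = "jitai_pipeline_error", parent = e)
  })
}

#' Run the full trial analysis pipeline
#'
#' Orchestrates simulate (or load), preprocess, weekly outcome tests,
#' change-point prompt-effect analysis and report rendering. With an
#' `out_dir` set, writes the weekly-outcome table, both test-result tables,
#' the formatted outcome and change-point tables, exclusion/analysis logs
#' and a machine-readable run manifest; reruns with the same configuration
#' and seed are byte-identical. A failing stage aborts with the stage named;
#' outputs from completed stages are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `trial` (when simulated), `daily`,
#'   `weekly`, `weekly_tests`, `day_effects`, `weekly_effects`,
#'   `effect_tests`, `tables`, `logs` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  input <- run_stage("input", {
    if (is.null(config$input_dir)) {
      tr <- simulate_trial(config$sim)
      list(trial = tr, minutes = tr$minutes)
    } else {
      list(trial = NULL,
           minutes = read_canonical_csv(config$input_dir)$minutes)
    }
  })
  trial <- input$trial
  minutes <- input$minutes

  pre <- run_stage("preprocess", {
    daily <- summarize_days(minutes, config$hr_moderate_threshold)
    split_days <- exclude_outlier_days(
      daily[!daily$all_missing, ], config$mvpa_outlier_limit
    )
    tagged <- assign_periods(split_days$retained, config$trial_start)
    list(daily = daily, excluded = split_days$excluded,
         rejected = attr(tagged, "rejected"),
         weekly = aggregate_weekly(tagged),
         missingness = missingness_report(minutes))
  })

  weekly_tests <- run_stage("weekly_tests", {
    week_vs_baseline_suite(pre$weekly, n_boot = config$n_boot,
                           seed = config$seed, alpha = config$alpha)
  })

  cp <- run_stage("changepoint", {
    per_day <- prompt_effects_by_day(
      minutes, window_lengths = config$window_lengths,
      max_missing = config$max_missing
    )
    weekly_eff <- weekly_prompt_effect(per_day$effects, config$trial_start)
    tests <- prompt_effect_tests(weekly_eff, n_boot = config$n_boot,
                                 seed = derive_seed(config$seed, 1000),
                                 alpha = config$alpha)
    list(day_effects = per_day$effects, log = per_day$log,
         weekly_effects = weekly_eff, effect_tests = tests)
  })

  result <- run_stage("report", {
    tables <- render_tables(pre$weekly, cp$weekly_effects)
    manifest <- list(
      package = "jitai",
      package_version = as.character(utils::packageVersion("jitai")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      n_boot = config$n_boot,
      trial_start = as.character(config$trial_start),
      hr_moderate_threshold = config$hr_moderate_threshold,
      mvpa_outlier_limit = config$mvpa_outlier_limit,
      max_missing = config$max_missing,
      window_lengths = config$window_lengths,
      alpha = config$alpha,
      simulated = is.null(config$input_dir),
      sim_seed = if (is.null(config$input_dir)) config$sim$seed else NULL
    )
    out <- list(
      trial = trial, daily = pre$daily, weekly = pre$weekly,
      weekly_tests = weekly_tests, day_effects = cp$day_effects,
      weekly_effects = cp$weekly_effects, effect_tests = cp$effect_tests,
      tables = tables,
      logs = list(excluded_days = pre$excluded,
                  rejected_days = pre$rejected,
                  missingness = pre$missingness, changepoint = cp$log),
      manifest = manifest
    )
    if (!is.null(config$out_dir)) write_report_bundle(out, config$out_dir)
    out
  })
  invisible(result)
}

write_report_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    readr::write_csv(x, file.path(dir, name), na = "")
  }
  wr(result$weekly, "weekly_outcomes.csv")
  wr(result$weekly_tests, "weekly_tests.csv")
  wr(result$weekly_effects, "prompt_effects_weekly.csv")
  wr(result$effect_tests, "prompt_effect_tests.csv")
  wr(result$tables$outcomes, "table_outcomes.csv")
  wr(result$tables$changepoints, "table_changepoints.csv")
  writeLines(result$tables$text, file.path(dir, "tables.txt"))
  jsonlite::write_json(
    list(excluded_days = result$logs$excluded_days,
         changepoint_log = result$logs$changepoint,
         flagged_missingness = result$logs$missingness$flagged),
    file.path(dir, "logs.json"), dataframe = "rows", na = "null",
    digits = NA
  )
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

fmt_mean_sd <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (all(is.na(x))) return("--")
  sprintf("%.2f (%.2f)", m, s)
}

#' Render the report tables
#'
#' Formats the weekly outcomes into the trial's two report shapes: the
#' outcome table (one block per outcome, one row per period, mean daily
#' value with the between-participant SD in parentheses) and the
#' change-point table (one block per signal and window length, per-period
#' pre-window mean, post-window mean, and mean increase per minute with SD).
#'
#' @param weekly Weekly outcome tibble from [aggregate_weekly()].
#' @param weekly_effects Weekly effect tibble from [weekly_prompt_effect()];
#'   NULL renders the outcome table only.
#' @return List with tibbles `outcomes` and `changepoints`, plus `text`, a
#'   human-readable rendering.
#' @export
render_tables <- function(weekly, weekly_effects = NULL) {
  outcome_labels <- c(
    sedentary_minutes = "Sedentary behavior (minutes per day)",
    met_mvpa_minutes = "MVPA based on MET (minutes per day)",
    hr_mvpa_minutes = "MVPA based on HR (minutes per day)",
    step_count = "Step count (steps per day)"
  )
  periods <- levels(factor(weekly$period))
  out_rows <- list()
  for (outcome in names(outcome_labels)) {
    for (per in periods) {
      vals <- weekly[[outcome]][weekly$period == per]
      out_rows[[length(out_rows) + 1L]] <- tibble(
        outcome = outcome_labels[[outcome]], period = per,
        mean_sd = fmt_mean_sd(vals)
      )
    }
  }
  outcomes <- if (length(out_rows) == 0) {
    tibble(outcome = character(), period = character(),
           mean_sd = character())
  } else {
    dplyr::bind_rows(out_rows)
  }

  changepoints <- tibble(
    signal = character(), window = integer(), period = character(),
    minutes_before = numeric(), minutes_after = numeric(),
    increase_per_minute = character()
  )
  if (!is.null(weekly_effects) && nrow(weekly_effects) > 0) {
    changepoints <- weekly_effects |>
      dplyr::group_by(.data$signal, .data$window, .data$period) |>
      dplyr::summarise(
        minutes_before = mean(.data$pre_mean, na.rm = TRUE),
        minutes_after = mean(.data$post_mean, na.rm = TRUE),
        increase_per_minute = fmt_mean_sd(.data$mean_delta),
        .groups = "drop"
      ) |>
      dplyr::arrange(dplyr::desc(.data$signal), dplyr::desc(.data$window),
                     .data$period)
  }

  text <- c(
    "Outcome measures during the baseline and intervention periods",
    sprintf("  %-45s %-9s %s", "Outcome", "Period", "Mean (SD) per day"),
    sprintf("  %-45s %-9s %s", outcomes$outcome, outcomes$period,
            outcomes$mean_sd),
    "",
    "Change-point analysis results",
    sprintf("  %-12s %-7s %-9s %12s %12s  %s", "Signal", "Window",
            "Period", "Before", "After", "Increase/min (SD)")
  )
  if (nrow(changepoints) > 0) {
    text <- c(text, sprintf(
      "  %-12s %-7d %-9s %12.3f %12.3f  %s",
      changepoints$signal, changepoints$window,
      as.character(changepoints$period), changepoints$minutes_before,
      changepoints$minutes_after, changepoints$increase_per_minute
    ))
  }
  list(outcomes = outcomes, changepoints = changepoints, text = text)
}
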