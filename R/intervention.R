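#' Goal state for the adaptive weekly goals
#'
#' Each participant carries two personalized daily goals: a step-count goal
#' and a heart-rate-zone MVPA ("active zone minutes") goal. Goals are
#' strictly positive and never decrease across weeks.
#'
#' @param step_goal Daily step goal (positive).
#' @param azm_goal Daily HR-MVPA minute goal (positive).
#' @param week_index Week counter (0 = goals set after baseline).
#' @return A list of class `goal_state`.
#' @export
goal_state <- function(step_goal, azm_goal, week_index = 0L) {
  if (!is.numeric(step_goal) || step_goal <= 0) {
    stop_field("step_goal", "must be a positive number")
  }
  if (!is.numeric(azm_goal) || azm_goal <= 0) {
    stop_field("azm_goal", "must be a positive number")
  }
  structure(
    list(step_goal = as.integer(round_half_up(step_goal)),
         azm_goal = as.integer(round_half_up(azm_goal)),
         week_index = as.integer(week_index)),
    class = "goal_state"
  )
}

#' @export
print.goal_state <- function(x, ...) {
  cat(sprintf("<goal_state> week %d: %s steps/day, %d AZM/day\n",
              x$week_index, format(x$step_goal, big.mark = ","),
              x$azm_goal))
  invisible(x)
}

# Single-goal update rule: a 5% raise on the achieved average when the
# previous goal was met on average, otherwise the goal is held.
update_one_goal <- function(prev_goal, achieved) {
  if (achieved >= prev_goal) {
    as.integer(round_half_up(1.05 * achieved))
  } else {
    as.integer(prev_goal)
  }
}

#' Update weekly goals from the previous week's achievement
#'
#' If the average daily value achieved during the previous week met or
#' exceeded the previous goal, the new goal is a 5% increase on that achieved
#' average (rounded half up); an underperforming participant keeps the same
#' goal. Applied independently to the step and AZM goals.
#'
#' @param prev A [goal_state()].
#' @param avg_daily_steps Average daily steps achieved last week (>= 0).
#' @param avg_daily_azm Average daily HR-MVPA minutes achieved last week
#'   (>= 0); omit to update only the step goal.
#' @return The new `goal_state` with `week_index` incremented.
#' @export
update_weekly_goal <- function(prev, avg_daily_steps, avg_daily_azm = NULL) {
  stopifnot(inherits(prev, "goal_state"))
  if (!is.numeric(avg_daily_steps) || avg_daily_steps < 0) {
    stop_field("avg_daily_steps", "must be >= 0")
  }
  new_azm <- prev$azm_goal
  if (!is.null(avg_daily_azm)) {
    if (!is.numeric(avg_daily_azm) || avg_daily_azm < 0) {
      stop_field("avg_daily_azm", "must be >= 0")
    }
    new_azm <- update_one_goal(prev$azm_goal, avg_daily_azm)
  }
  structure(
    list(step_goal = update_one_goal(prev$step_goal, avg_daily_steps),
         azm_goal = new_azm,
         week_index = prev$week_index + 1L),
    class = "goal_state"
  )
}

#' The five prompt-framing tiers
#'
#' Messages are framed by the percentage of the daily step goal reached so
#' far, in five bands with inclusive lower bounds: <40%, >=40%, >=60%,
#' >=80%, >=100%.
#'
#' @return Tibble with columns `label` and `lower_bound_pct`.
#' @export
prompt_tiers <- function() {
  tibble(
    label = c("LT40", "GE40", "GE60", "GE80", "GE100"),
    lower_bound_pct = c(0, 40, 60, 80, 100)
  )
}

#' Classify the prompt framing tier
#'
#' @param steps_so_far Steps accumulated before the prompt (>= 0).
#' @param goal Daily step goal (> 0).
#' @return One row of [prompt_tiers()] with the achieved percentage added
#'   (`pct_of_goal`). Tiers partition `[0, Inf)`: the band whose half-open
#'   interval `[lower, next)` contains the percentage, with the top tier
#'   unbounded.
#' @export
classify_prompt_tier <- function(steps_so_far, goal) {
  if (!is.numeric(goal) || goal <= 0) stop_field("goal", "must be > 0")
  if (!is.numeric(steps_so_far) || steps_so_far < 0) {
    stop_field("steps_so_far", "must be >= 0")
  }
  pct <- 100 * steps_so_far / goal
  tiers <- prompt_tiers()
  row <- tiers[max(which(pct >= tiers$lower_bound_pct)), ]
  row$pct_of_goal <- pct
  row
}

#' Built-in prompt template pool
#'
#' Loads the packaged pool of positively framed activity-suggestion
#' templates: framing texts keyed by tier (each containing `{name}`,
#' `{steps}`, `{pct}` and `{benefit}` slots) and a pool of WHO-based health
#' benefit sentences.
#'
#' @return List with elements `framings` (named list of character vectors,
#'   one per tier) and `benefits` (character vector).
#' @export
default_prompt_templates <- function() {
  path <- system.file("extdata", "prompt_templates.json", package = "jitai")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Render a personalized activity prompt
#'
#' Builds the daily prompt message from its five variables: participant
#' name, steps so far, percentage of the daily goal, a health benefit drawn
#' from the template pool, and the tier-keyed framing.
#'
#' @param name Participant name (non-empty).
#' @param steps_so_far Steps accumulated before the prompt.
#' @param goal Daily step goal.
#' @param templates Template pool as from [default_prompt_templates()].
#' @param seed Integer seed; the framing template and benefit are drawn
#'   reproducibly under it.
#' @return List of class `prompt_message` with fields `name`,
#'   `steps_so_far`, `pct_of_goal`, `tier`, `benefit`, `framing` and the
#'   rendered `text`.
#' @export
render_prompt <- function(name, steps_so_far, goal,
                          templates = default_prompt_templates(),
                          seed = 1L) {
  if (!is.character(name) || !nzchar(name)) {
    stop_field("name", "must be a non-empty string")
  }
  tier <- classify_prompt_tier(steps_so_far, goal)
  pool <- templates$framings[[tier$label]]
  if (is.null(pool) || length(pool) == 0) {
    stop_field("templates", sprintf("no framing templates for tier %s",
                                    tier$label))
  }
  if (length(templates$benefits) == 0) {
    stop_field("templates", "benefit pool is empty")
  }
  draws <- with_seed(seed, {
    c(sample.int(length(pool), 1), sample.int(length(templates$benefits), 1))
  })
  benefit <- templates$benefits[draws[2]]
  pct <- floor(tier$pct_of_goal)
  framing <- pool[draws[1]]
  text <- fill_template(framing, list(
    name = name,
    steps = format(steps_so_far, big.mark = ","),
    pct = pct,
    benefit = benefit
  ))
  structure(
    list(name = name, steps_so_far = steps_so_far, pct_of_goal = pct,
         tier = tier$label, benefit = benefit, framing = framing,
         text = text),
    class = "prompt_message"
  )
}

#' @export
print.prompt_message <- function(x, ...) {
  cat(sprintf("<prompt_message> tier %s (%d%% of goal)\n", x$tier,
              x$pct_of_goal))
  cat(strwrap(x$text, width = 72, prefix = "  "), sep = "\n")
  invisible(x)
}

#' Reminder-to-move decision
#'
#' During the after-school window (4 PM to 9 PM, half-open `[16, 21)`), an
#' hour with no steps and no heart-rate-elevating activity triggers a
#' reminder to take at least 250 steps by the end of the hour.
#'
#' @param hour_of_day Clock hour, 0-23.
#' @param steps_this_hour Steps accumulated within the hour so far.
#' @param elevated_hr_this_hour Logical: any HR-elevating activity this hour.
#' @return List with `remind` (logical) and `step_target` (250).
#' @export
should_remind <- function(hour_of_day, steps_this_hour,
                          elevated_hr_this_hour = FALSE) {
  if (hour_of_day < 0 || hour_of_day > 23) {
    stop_field("hour_of_day", "must be in 0..23")
  }
  remind <- hour_of_day >= 16 && hour_of_day < 21 &&
    steps_this_hour == 0 && !isTRUE(elevated_hr_this_hour)
  list(remind = remind, step_target = 250L)
}

#' Weekly voucher reward from consecutive goal-met days
#'
#' The reward depends on the longest run of consecutive days in line with or
#' above the personalized goals within the week: 3, 5 or 7 consecutive days
#' pay a 15, 30 or 40 euro voucher respectively. Runs of 4 or 6 days pay the
#' next-lower tier; runs below 3 pay nothing.
#'
#' @param goal_met Logical vector of exactly 7 daily goal-met flags.
#' @return Voucher value in euros (0, 15, 30 or 40).
#' @export
compute_reward <- function(goal_met) {
  if (length(goal_met) != 7 || !is.logical(goal_met) || anyNA(goal_met)) {
    stop_field("goal_met", "must be exactly 7 non-missing logical flags")
  }
  runs <- rle(goal_met)
  longest <- max(c(0L, runs$lengths[runs$values]))
  if (longest >= 7) 40 else if (longest >= 5) 30 else if (longest >= 3) 15
  else 0
}

#' WHO physical-activity sufficiency for a day
#'
#' A day meets the WHO recommendation for adolescents when it has at least
#' 60 minutes of moderate-to-vigorous activity, or the associated 11,700
#' daily steps.
#'
#' @param mvpa_minutes MVPA minutes for the day.
#' @param steps Step count for the day.
#' @return Logical (vectorized).
#' @export
who_sufficient <- function(mvpa_minutes, steps) {
  mvpa_minutes >= 60 | steps >= 11700
}

#' Eligibility screen for trial participation
#'
#' Eligible participants are adolescents aged 16-18 with low-to-moderate
#' self-reported activity (PAQ-A summary score of 3 or less on the 1-5
#' scale) who neither already use an activity tracker nor have constraints
#' toward performing physical activity.
#'
#' @param paq_a_score PAQ-A summary score in `[1, 5]`.
#' @param age Age in years.
#' @param owns_active_tracker Logical: owns and actively uses a tracker.
#' @param pa_constraint Logical: any constraint toward performing PA.
#' @return Logical: eligible or not.
#' @export
screen_participant <- function(paq_a_score, age,
                               owns_active_tracker = FALSE,
                               pa_constraint = FALSE) {
  if (!is.numeric(paq_a_score) || paq_a_score < 1 || paq_a_score > 5) {
    stop_field("paq_a_score", "must lie in [1, 5]")
  }
  paq_a_score <= 3 && age >= 16 && age <= 18 &&
    !isTRUE(owns_active_tracker) && !isTRUE(pa_constraint)
}
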