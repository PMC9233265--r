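#' Write a trial dataset to the canonical on-disk form
#'
#' Minute records go to `minutes.csv` with columns `participant_id`,
#' `timestamp` (ISO 8601, minute resolution, UTC), `steps`, `heart_rate`
#' (empty when missing) and `intensity` (empty when missing) — one row per
#' participant-minute. The prompt log and the ground-truth effect tables are
#' written as JSON sidecars (`prompts.json`, `ground_truth.json`).
#'
#' @param trial A `jitai_trial` from [simulate_trial()], or a bare minute
#'   tibble (then no sidecars are written).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_canonical_csv <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  minutes <- if (inherits(trial, "jitai_trial")) trial$minutes else trial
  out <- tibble(
    participant_id = minutes$participant_id,
    timestamp = format(
      as.POSIXct(minutes$date, tz = "UTC") + minutes$minute * 60,
      "%Y-%m-%dT%H:%M:%S", tz = "UTC"
    ),
    steps = minutes$steps,
    heart_rate = minutes$heart_rate,
    intensity = minutes$intensity
  )
  paths <- file.path(dir, "minutes.csv")
  readr::write_csv(out, paths, na = "")
  if (inherits(trial, "jitai_trial")) {
    pj <- file.path(dir, "prompts.json")
    gj <- file.path(dir, "ground_truth.json")
    prompts <- trial$prompts
    prompts$date <- as.character(prompts$date)
    jsonlite::write_json(prompts, pj, dataframe = "rows", na = "null")
    injections <- trial$injections
    injections$date <- as.character(injections$date)
    injections$period <- as.character(injections$period)
    jsonlite::write_json(
      list(effects = trial$effects, injections = injections),
      gj, dataframe = "rows", na = "null", digits = NA
    )
    paths <- c(paths, pj, gj)
  }
  invisible(paths)
}

#' Read a canonical trial dataset back from disk
#'
#' Inverse of [write_canonical_csv()]: `read_canonical_csv(write(x))`
#' restores the minute records (and, when the sidecars are present, the
#' prompt log and ground-truth tables) exactly.
#'
#' @param dir Directory holding `minutes.csv` and optional JSON sidecars.
#' @return A list with `minutes` (tibble) and, if present, `prompts`,
#'   `effects` and `injections`.
#' @export
read_canonical_csv <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "minutes.csv") else dir
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path),
          class = "jitai_io_error")
  }
  required <- c("participant_id", "timestamp", "steps", "heart_rate",
                "intensity")
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c"),
                                  show_col_types = FALSE))
  missing_cols <- setdiff(required, header)
  if (length(missing_cols) > 0) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "jitai_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      timestamp = readr::col_datetime(format = "%Y-%m-%dT%H:%M:%S"),
      steps = readr::col_integer(),
      heart_rate = readr::col_double(),
      intensity = readr::col_character()
    ),
    locale = readr::locale(tz = "UTC"), na = ""
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed rows in %s (first at line %d: %s)",
                  path, probs$row[1] + 1L, probs$expected[1]),
          class = "jitai_io_error")
  }
  minutes <- tibble(
    participant_id = raw$participant_id,
    date = as.Date(raw$timestamp, tz = "UTC"),
    minute = as.integer(format(raw$timestamp, "%H", tz = "UTC")) * 60L +
      as.integer(format(raw$timestamp, "%M", tz = "UTC")),
    steps = raw$steps,
    heart_rate = raw$heart_rate,
    intensity = raw$intensity
  )
  out <- list(minutes = minutes)

  dirn <- if (dir.exists(dir)) dir else dirname(path)
  pj <- file.path(dirn, "prompts.json")
  if (file.exists(pj)) {
    pr <- as_tibble(jsonlite::read_json(pj, simplifyVector = TRUE))
    if (nrow(pr) > 0) {
      pr$date <- as.Date(pr$date)
      pr$delivery_minute <- as.integer(pr$delivery_minute)
    }
    out$prompts <- pr
  }
  gj <- file.path(dirn, "ground_truth.json")
  if (file.exists(gj)) {
    gt <- jsonlite::read_json(gj, simplifyVector = TRUE)
    out$effects <- as_tibble(gt$effects)
    inj <- as_tibble(gt$injections)
    if (nrow(inj) > 0) inj$date <- as.Date(inj$date)
    out$injections <- inj
  }
  out
}

#' Read Fitabase-style minute exports
#'
#' Parses the minute-level export dialect of the Fitabase platform: one file
#' per stream with columns `Id` and `ActivityMinute` (formatted
#' `M/D/YYYY h:mm:ss AM/PM`), plus `Steps` (step file), `Value` (heart-rate
#' file) or `Intensity` (0-3 intensity file). Streams are merged on
#' `Id` + timestamp into the canonical minute tibble. When no intensity file
#' is given, intensity is derived from steps and heart rate via
#' [classify_intensity()].
#'
#' @param steps_file Path to the minute-steps CSV.
#' @param hr_file Optional path to the minute-heart-rate CSV.
#' @param intensity_file Optional path to the minute-intensity CSV
#'   (0 = sedentary, 1 = light, 2 = moderate, 3 = vigorous).
#' @param moderate_cutoff,vigorous_cutoff,elevated_hr_cutoff Cut-offs for
#'   the derived intensity when no intensity file is supplied.
#' @return Canonical minute tibble (`participant_id`, `date`, `minute`,
#'   `steps`, `heart_rate`, `intensity`).
#' @export
read_fitabase_minutes <- function(steps_file, hr_file = NULL,
                                  intensity_file = NULL,
                                  moderate_cutoff = 60,
                                  vigorous_cutoff = 130,
                                  elevated_hr_cutoff = 100) {
  parse_one <- function(path, value_col) {
    if (!file.exists(path)) {
      abort(sprintf("input file not found: %s", path),
            class = "jitai_io_error")
    }
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
    need <- c("Id", "ActivityMinute", value_col)
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      abort(sprintf("%s: missing required column(s): %s", path,
                    paste(miss, collapse = ", ")),
            class = "jitai_io_error")
    }
    ts <- as.POSIXct(raw$ActivityMinute, format = "%m/%d/%Y %I:%M:%S %p",
                     tz = "UTC")
    bad <- which(is.na(ts) & !is.na(raw$ActivityMinute))
    if (length(bad) > 0) {
      abort(sprintf("%s: malformed timestamp at data line %d: '%s'",
                    path, bad[1], raw$ActivityMinute[bad[1]]),
            class = "jitai_io_error")
    }
    tibble(
      participant_id = as.character(raw$Id),
      date = as.Date(ts, tz = "UTC"),
      minute = as.integer(format(ts, "%H", tz = "UTC")) * 60L +
        as.integer(format(ts, "%M", tz = "UTC")),
      value = as.numeric(raw[[value_col]])
    ) |>
      stats::setNames(c("participant_id", "date", "minute", value_col))
  }

  out <- parse_one(steps_file, "Steps")
  out <- dplyr::rename(out, steps = "Steps")
  out$steps <- as.integer(out$steps)
  if (!is.null(hr_file)) {
    hr <- dplyr::rename(parse_one(hr_file, "Value"), heart_rate = "Value")
    out <- dplyr::full_join(out, hr,
                            by = c("participant_id", "date", "minute"))
  } else {
    out$heart_rate <- NA_real_
  }
  if (!is.null(intensity_file)) {
    it <- dplyr::rename(parse_one(intensity_file, "Intensity"),
                        code = "Intensity")
    it$intensity <- INTENSITY_LEVELS[it$code + 1L]
    it$code <- NULL
    out <- dplyr::full_join(out, it,
                            by = c("participant_id", "date", "minute"))
  } else {
    out$intensity <- classify_intensity(out$steps, out$heart_rate,
                                        moderate_cutoff, vigorous_cutoff,
                                        elevated_hr_cutoff)
  }
  dplyr::arrange(out, .data$participant_id, .data$date, .data$minute)
}
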