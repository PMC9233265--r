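#' Round half away from zero
#'
#' Commercial rounding used for goal updates: `round_half_up(10500.5)` is
#' 10501, unlike base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @return `x` rounded to the nearest integer, ties away from zero.
#' @export
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Fill "{name}"-style placeholders in a template string.
fill_template <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{", key, "}"), values[[key]], template,
                     fixed = TRUE)
  }
  template
}

stop_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "jitai_config_error")
}

period_labels <- function(n_periods = 4L) {
  c("baseline", paste0("week", seq_len(n_periods - 1L)))
}

period_of_day_index <- function(day_index, n_periods = 4L) {
  lv <- period_labels(n_periods)
  factor(lv[day_index %/% 7L + 1L], levels = lv)
}

# Derive a stream-specific seed from a user seed, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) + 104729 * offset) %% 2147483647
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
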