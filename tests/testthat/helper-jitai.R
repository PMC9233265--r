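# Shared fixtures and independent oracles, built in code.

# One participant-day minute tibble with constant or supplied signals.
make_day <- function(steps = 0L, heart_rate = 80, pid = "P01",
                     date = as.Date("2021-06-07"), intensity = NULL) {
  steps <- as.integer(rep_len(steps, 1440L))
  heart_rate <- as.numeric(rep_len(heart_rate, 1440L))
  if (is.null(intensity)) {
    intensity <- classify_intensity(steps, heart_rate)
  } else {
    intensity <- rep_len(intensity, 1440L)
  }
  tibble::tibble(
    participant_id = pid, date = date, minute = 0:1439,
    steps = steps, heart_rate = heart_rate, intensity = intensity
  )
}

# Small, fast trial configuration for pipeline-level tests.
small_config <- function(seed = 1L, ...) {
  sim_config(n_participants = 4L, seed = seed, ...)
}

# Brute-force longest run of TRUE flags (independent of rle).
oracle_longest_run <- function(flags) {
  best <- 0L
  cur <- 0L
  for (f in flags) {
    cur <- if (isTRUE(f)) cur + 1L else 0L
    if (cur > best) best <- cur
  }
  best
}

# Exhaustive single-split scan: minute-of-day (first index of the right
# segment) minimizing total SSE via direct segment sums, optionally
# restricted to splits at or after a cutoff minute. Ties -> earliest.
oracle_best_split_minute <- function(values, window_start = 900L,
                                     cutoff_minute = NULL) {
  n <- length(values)
  sse <- function(x) sum((x - mean(x))^2)
  best_k <- NA_integer_
  best_sse <- Inf
  for (k in 2:n) { # right segment starts at k
    minute <- window_start + k - 1L
    if (!is.null(cutoff_minute) && minute < cutoff_minute) next
    tot <- sse(values[1:(k - 1)]) + sse(values[k:n])
    if (tot < best_sse - 1e-12) {
      best_sse <- tot
      best_k <- k
    }
  }
  window_start + best_k - 1L
}

# Upper-tail Student-t probability by numerical quadrature of the density
# written out explicitly (independent of pt()).
oracle_t_upper <- function(t, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, t, Inf, rel.tol = 1e-10)$value
}
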