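#' Classic paired one-tailed t test
#'
#' Within-subject comparison of a week against baseline. Pairs with a
#' missing member are dropped listwise. Differences are oriented so that the
#' stated one-tailed alternative is positive: `d = week - baseline` for
#' `direction = "increase"`, `d = baseline - week` for `"decrease"`. The
#' statistic is `t = mean(d) / (sd(d)/sqrt(n))` and the p value is the upper
#' tail of Student's t with `n - 1` degrees of freedom.
#'
#' @param baseline,week Paired numeric vectors (same participants, same
#'   order).
#' @param direction One-tailed alternative: `"increase"` or `"decrease"`
#'   (week relative to baseline).
#' @return One-row tibble: `n`, `df`, `t` (oriented), `p_classic`,
#'   `mean_diff` (raw `mean(week - baseline)`, unoriented).
#' @export
paired_t_one_tailed <- function(baseline, week,
                                direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (length(baseline) != length(week)) {
    abort("baseline and week must have equal length",
          class = "jitai_stats_error")
  }
  keep <- !is.na(baseline) & !is.na(week)
  b <- baseline[keep]
  w <- week[keep]
  n <- length(b)
  if (n < 2) {
    abort("fewer than 2 complete pairs", class = "jitai_stats_error")
  }
  d <- if (direction == "increase") w - b else b - w
  s <- sd(d)
  if (s == 0) {
    abort("zero-variance differences: paired t test is degenerate",
          class = "jitai_degenerate_error")
  }
  t_obs <- mean(d) / (s / sqrt(n))
  tibble(
    n = n, df = n - 1L, t = t_obs,
    p_classic = pt(t_obs, df = n - 1, lower.tail = FALSE),
    mean_diff = mean(w - b)
  )
}

# Bootstrap-t distribution of null-centered, sorted differences. Sorting
# makes the resampling - and hence the p value - invariant to participant
# order.
boot_t_stats <- function(d, n_boot, seed) {
  n <- length(d)
  d0 <- sort(d - mean(d))
  with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    x <- matrix(d0[idx], nrow = n)
    m <- colMeans(x)
    v <- (colSums(x^2) - n * m^2) / (n - 1)
    v[v < 0] <- 0 # numerical guard
    s <- sqrt(v)
    t_star <- ifelse(s > 0, m / (s / sqrt(n)),
                     ifelse(m == 0, 0, sign(m) * Inf))
    t_star
  })
}

#' Bootstrapped paired one-tailed t test
#'
#' Small-sample companion to [paired_t_one_tailed()]: the oriented paired
#' differences are centered to the null, resampled with replacement
#' `n_boot` times, and the t statistic recomputed on each resample. The
#' bootstrap p value is `(1 + #(t* >= t_obs)) / (n_boot + 1)`, which can
#' never be exactly zero. Deterministic under a fixed seed and invariant to
#' participant order.
#'
#' @inheritParams paired_t_one_tailed
#' @param n_boot Number of bootstrap resamples (default 10,000).
#' @param seed Integer seed for the resampling.
#' @return One-row tibble: `n`, `df`, `t`, `p_classic`, `p_bootstrap`,
#'   `mean_diff`, `n_boot`, `seed`.
#' @export
bootstrap_paired_t <- function(baseline, week,
                               direction = c("increase", "decrease"),
                               n_boot = 10000L, seed = 1L) {
  direction <- match.arg(direction)
  if (n_boot < 1) stop_field("n_boot", "must be >= 1")
  classic <- paired_t_one_tailed(baseline, week, direction)
  keep <- !is.na(baseline) & !is.na(week)
  d <- if (direction == "increase") {
    week[keep] - baseline[keep]
  } else {
    baseline[keep] - week[keep]
  }
  t_star <- boot_t_stats(d, n_boot, seed)
  classic$p_bootstrap <- (1 + sum(t_star >= classic$t)) / (n_boot + 1)
  classic$n_boot <- as.integer(n_boot)
  classic$seed <- as.integer(seed)
  classic[, c("n", "df", "t", "p_classic", "p_bootstrap", "mean_diff",
              "n_boot", "seed")]
}

#' Week-versus-baseline test suite over all outcomes
#'
#' Runs the classic and bootstrapped paired one-tailed t tests for every
#' outcome and every intervention week against baseline, with listwise
#' deletion per comparison (so degrees of freedom may differ between
#' comparisons). Significance is flagged at the uncorrected `alpha` on the
#' classic p value; no multiplicity correction is applied. Comparisons with
#' fewer than 2 complete pairs, or with zero-variance differences, are
#' reported as not computable rather than failing.
#'
#' @param weekly Weekly outcome tibble from [aggregate_weekly()].
#' @param directions Named character vector mapping outcome columns to their
#'   one-tailed alternative (defaults: sedentary decreases, the activity
#'   outcomes increase).
#' @param n_boot,seed Bootstrap settings; each comparison gets a seed
#'   derived deterministically from `seed`.
#' @param alpha Significance level (default .05).
#' @return Tibble: `outcome`, `period`, `direction`, `n`, `df`, `t`,
#'   `p_classic`, `p_bootstrap`, `mean_diff`, `significant`, `note`.
#' @export
week_vs_baseline_suite <- function(weekly, directions = DEFAULT_DIRECTIONS,
                                   n_boot = 10000L, seed = 1L,
                                   alpha = 0.05) {
  periods <- setdiff(levels(factor(weekly$period)), "baseline")
  base <- weekly[weekly$period == "baseline", ]
  rows <- list()
  i <- 0L
  for (outcome in names(directions)) {
    for (per in periods) {
      i <- i + 1L
      wk <- weekly[weekly$period == per, ]
      m <- match(base$participant_id, wk$participant_id)
      b <- base[[outcome]]
      w <- wk[[outcome]][m]
      res <- tryCatch(
        bootstrap_paired_t(b, w, directions[[outcome]], n_boot,
                           derive_seed(seed, i)),
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
      res$outcome <- outcome
      res$period <- per
      res$direction <- directions[[outcome]]
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p_classic) & out$p_classic < alpha
  out[, c("outcome", "period", "direction", "n", "df", "t", "p_classic",
          "p_bootstrap", "mean_diff", "significant", "note")]
}
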