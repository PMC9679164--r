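#' Simulated psychophysical observer
#'
#' A Weibull psychometric observer for forced-choice contrast tasks:
#' `P(correct | c) = guess + (1 - guess) (1 - lapse) (1 - exp(-(c/alpha)^beta))`,
#' monotone non-decreasing in contrast and bounded in
#' `[guess, 1 - lapse (1 - guess)]`.
#'
#' @param alpha Weibull threshold parameter (contrast units).
#' @param beta Psychometric slope.
#' @param guess_rate Chance performance: 0.25 for the 4AFC square task,
#'   0.5 for the two-alternative ridge task.
#' @param lapse_rate Lapse rate in [0, 0.1].
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(alpha, beta = 3, guess_rate = 0.25,
                           lapse_rate = 0.02) {
  stopifnot(alpha > 0, beta > 0, guess_rate >= 0, guess_rate < 1,
            lapse_rate >= 0, lapse_rate <= 0.1)
  structure(list(alpha = alpha, beta = beta, guess_rate = guess_rate,
                 lapse_rate = lapse_rate), class = "observer_model")
}

#' Probability correct at a given contrast
#' @param observer An [observer_model()].
#' @param contrast Michelson contrast (>= 0), vectorized.
#' @return P(correct).
#' @export
p_correct <- function(observer, contrast) {
  f <- 1 - exp(-(contrast / observer$alpha)^observer$beta)
  observer$guess_rate +
    (1 - observer$guess_rate) * (1 - observer$lapse_rate) * f
}

#' Default staircase level-to-contrast table
#'
#' Maps staircase steps 1..21 (1 = highest contrast) to mean L+M Michelson
#' contrasts, log-spaced over two decades from `c_max` down to `c_max/100`.
#'
#' @param c_max Contrast at level 1 (default 0.52, near the display's gamut
#'   ceiling for the mean L/M contrast).
#' @param n_levels Number of steps (default 21).
#' @param decades Log range (default 2).
#' @return Data frame with `level` and `contrast`.
#' @export
level_contrast_table <- function(c_max = 0.52, n_levels = 21, decades = 2) {
  level <- seq_len(n_levels)
  data.frame(level = level,
             contrast = c_max * 10^(-decades * (level - 1) / (n_levels - 1)))
}

#' Staircase configuration
#'
#' The 1-up/1-down rule over ordered contrast steps: a correct response
#' steps toward lower contrast (higher level number), an incorrect response
#' (or a "stimulus not visible" report) toward higher contrast, clamped at
#' the extremes. The staircase stops after `min_reversals` reversals
#' (14 for the square task, 8 for the ridge task) or once more than
#' `max_correct_at_floor` correct responses have occurred at the lowest
#' contrast (ceiling performance).
#'
#' @param levels Ordered level numbers (default 1:21, 1 = highest contrast).
#' @param start_level Starting level (default 1, the brightest contrast).
#' @param min_reversals Reversal stop criterion.
#' @param max_correct_at_floor Correct-at-lowest-contrast stop criterion
#'   (default 8: stops after more than 8).
#' @param n_reversals_for_threshold Reversals averaged for the threshold
#'   (default 6).
#' @param max_trials Safety cap on trial count.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(levels = 1:21, start_level = 1,
                             min_reversals = 14, max_correct_at_floor = 8,
                             n_reversals_for_threshold = 6,
                             max_trials = 1000) {
  stopifnot(min_reversals > 0, max_correct_at_floor > 0,
            start_level %in% levels)
  structure(list(levels = levels, start_level = start_level,
                 min_reversals = min_reversals,
                 max_correct_at_floor = max_correct_at_floor,
                 n_reversals_for_threshold = n_reversals_for_threshold,
                 max_trials = max_trials), class = "staircase_config")
}

#' Run one adaptive staircase
#'
#' Simulates a 1-up/1-down staircase for an observer, using a
#' level-to-contrast table to evaluate the psychometric function. The
#' threshold estimate is the mean of the last `n_reversals_for_threshold`
#' reversal levels; if the ceiling stop fires (more than
#' `max_correct_at_floor` correct at the lowest contrast) the threshold is
#' the lowest-contrast level and the result is flagged `ceiling`.
#'
#' @param observer An [observer_model()], or a function `level -> P(correct)`
#'   for deterministic test observers.
#' @param config A [staircase_config()].
#' @param seed Integer seed (same seed, identical trial log).
#' @param contrast_table A [level_contrast_table()] covering all levels.
#' @return A list of class `staircase_result`: `trials` (data frame `trial`,
#'   `level`, `contrast`, `correct`), `reversal_levels`,
#'   `threshold_level` (step units), `threshold_contrast`, `ceiling`.
#' @export
run_staircase <- function(observer, config = staircase_config(), seed = 1,
                          contrast_table = level_contrast_table()) {
  p_at <- if (is.function(observer)) {
    function(level) observer(level)
  } else {
    function(level) {
      p_correct(observer, contrast_table$contrast[match(level,
                                                        contrast_table$level)])
    }
  }
  set.seed(seed)
  lv <- config$start_level
  lv_min <- min(config$levels); lv_max <- max(config$levels)
  trials <- integer(0); responses <- logical(0)
  reversals <- numeric(0)
  correct_at_floor <- 0L
  last_dir <- 0L
  ceiling_flag <- FALSE
  for (trial in seq_len(config$max_trials)) {
    correct <- stats::runif(1) < p_at(lv)
    trials <- c(trials, lv); responses <- c(responses, correct)
    if (correct && lv == lv_max) correct_at_floor <- correct_at_floor + 1L
    if (correct_at_floor > config$max_correct_at_floor) {
      ceiling_flag <- TRUE
      break
    }
    dir <- if (correct) 1L else -1L  # +1 = toward lower contrast
    if (last_dir != 0L && dir != last_dir) reversals <- c(reversals, lv)
    last_dir <- dir
    lv <- min(lv_max, max(lv_min, lv + dir))
    if (length(reversals) >= config$min_reversals) break
  }
  k <- config$n_reversals_for_threshold
  thr_level <- if (ceiling_flag) {
    lv_max
  } else if (length(reversals) == 0) {
    NA_real_
  } else {
    mean(utils::tail(reversals, k))
  }
  structure(list(
    trials = data.frame(trial = seq_along(trials), level = trials,
                        contrast = contrast_table$contrast[
                          match(trials, contrast_table$level)],
                        correct = responses),
    reversal_levels = reversals, threshold_level = thr_level,
    threshold_contrast = if (is.na(thr_level)) NA_real_ else
      threshold_in_contrast(thr_level, contrast_table),
    ceiling = ceiling_flag), class = "staircase_result")
}

#' Convert a step-unit threshold to Michelson contrast
#'
#' Linear interpolation of a (possibly fractional) staircase-step threshold
#' through the per-level contrast table.
#'
#' @param threshold_level Threshold in step units.
#' @param contrast_table A [level_contrast_table()].
#' @return The interpolated Michelson contrast.
#' @export
threshold_in_contrast <- function(threshold_level, contrast_table) {
  if (threshold_level < min(contrast_table$level) ||
      threshold_level > max(contrast_table$level)) {
    stop("threshold level outside the tabulated range")
  }
  stats::approx(contrast_table$level, contrast_table$contrast,
                xout = threshold_level)$y
}

#' Level at which an observer reaches 50% correct
#'
#' The convergence point of a 1-up/1-down staircase, in (fractional) step
#' units of the contrast table.
#'
#' @param observer An [observer_model()].
#' @param contrast_table A [level_contrast_table()].
#' @return Step-unit level at which `P(correct) = 0.5` (interpolated in log
#'   contrast), or `NA` if 50% lies outside the table.
#' @export
observer_p50_level <- function(observer, contrast_table = level_contrast_table()) {
  top <- 1 - observer$lapse_rate * (1 - observer$guess_rate)
  if (observer$guess_rate >= 0.5 || top <= 0.5) return(NA_real_)
  f50 <- (0.5 - observer$guess_rate) /
    ((1 - observer$guess_rate) * (1 - observer$lapse_rate))
  c50 <- observer$alpha * (-log(1 - f50))^(1 / observer$beta)
  if (c50 > max(contrast_table$contrast) ||
      c50 < min(contrast_table$contrast)) return(NA_real_)
  stats::approx(log(contrast_table$contrast), contrast_table$level,
                xout = log(c50))$y
}

#' 95% prediction interval for a new untreated-group measurement
#'
#' `mean +/- t_{(1+level)/2, n-1} * s * sqrt(1 + 1/n)`: the t-distribution
#' interval expected to contain a new draw from the same population.
#'
#' @param values Numeric vector of untreated thresholds (n >= 2).
#' @param level Coverage level (default 0.95).
#' @return Numeric `c(lo, hi)` (degenerate at the mean for zero variance).
#' @export
prediction_interval <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) return(c(m, m))
  half <- stats::qt((1 + level) / 2, df = n - 1) * s * sqrt(1 + 1 / n)
  c(m - half, m + half)
}

#' Classify a threshold against the untreated-group range
#'
#' Lower thresholds mean better contrast sensitivity, so a threshold
#' strictly below the interval is classified as improved beyond the
#' untreated range; boundary values count as within (closed interval).
#'
#' @param threshold Measured threshold (same units as the interval).
#' @param interval `c(lo, hi)` from [prediction_interval()].
#' @return `"improved beyond range"` or `"within untreated range"`.
#' @export
exceeds_untreated_range <- function(threshold, interval) {
  if (threshold < interval[1]) "improved beyond range"
  else "within untreated range"
}

#' Write a staircase trial log as CSV
#' @param result A [run_staircase()] result.
#' @param path Output path.
#' @export
write_staircase_log <- function(result, path) {
  utils::write.csv(result$trials, path, row.names = FALSE)
  invisible(path)
}
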