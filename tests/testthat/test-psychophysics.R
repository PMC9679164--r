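test_that("psychometric function respects its bounds and monotonicity", {
  obs <- observer_model(alpha = 0.1, beta = 3, guess_rate = 0.25,
                        lapse_rate = 0.05)
  cs <- seq(0, 1, by = 0.01)
  p <- p_correct(obs, cs)
  expect_equal(p[1], 0.25)
  expect_true(all(diff(p) >= 0))
  expect_lte(max(p), 1 - 0.05 * (1 - 0.25))
})

test_that("a step-function observer drives the staircase to its boundary", {
  # deterministic observer: always correct at levels 1..10, never above
  step_obs <- function(level) as.numeric(level <= 10)
  res <- run_staircase(step_obs, staircase_config(), seed = 1)
  expect_false(res$ceiling)
  expect_lt(abs(res$threshold_level - 10.5), 1)
})

test_that("an always-correct observer hits the ceiling stop", {
  res <- run_staircase(function(level) 1, staircase_config(), seed = 1)
  expect_true(res$ceiling)
  expect_equal(res$threshold_level, 21)
  # >8 correct at the lowest contrast: exactly 9 floor trials before stopping
  expect_equal(sum(res$trials$level == 21), 9)
})

test_that("staircases are reproducible under a fixed seed", {
  obs <- observer_model(alpha = 0.05, guess_rate = 0.25)
  r1 <- run_staircase(obs, staircase_config(), seed = 42)
  r2 <- run_staircase(obs, staircase_config(), seed = 42)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$threshold_level, r2$threshold_level)
})

test_that("step thresholds convert to contrast by table interpolation", {
  tab <- level_contrast_table()
  expect_equal(threshold_in_contrast(5, tab), tab$contrast[5])
  expect_equal(threshold_in_contrast(5.5, tab),
               mean(tab$contrast[5:6]))
  expect_error(threshold_in_contrast(25, tab), "range")
  # round trip: contrast -> nearest level -> contrast
  for (lv in c(3, 11, 19)) {
    c0 <- tab$contrast[lv]
    nearest <- tab$level[which.min(abs(tab$contrast - c0))]
    expect_equal(tab$contrast[nearest], c0)
  }
})

test_that("1-up/1-down staircases converge on the 50%-correct level", {
  tab <- level_contrast_table()
  obs <- observer_model(alpha = 0.05, beta = 3, guess_rate = 0.25,
                        lapse_rate = 0.02)
  target <- observer_p50_level(obs, tab)
  expect_false(is.na(target))
  thr <- vapply(1:500, function(i) {
    run_staircase(obs, staircase_config(), seed = i,
                  contrast_table = tab)$threshold_level
  }, numeric(1))
  expect_lt(abs(mean(thr) - target), 1)
})

test_that("trial counts for a plausible observer bracket the reported means", {
  obs <- observer_model(alpha = 0.05, beta = 3, guess_rate = 0.25)
  n_trials <- vapply(1:100, function(i) {
    nrow(run_staircase(obs, staircase_config(), seed = i)$trials)
  }, numeric(1))
  expect_gt(mean(n_trials), 27 / 2)
  expect_lt(mean(n_trials), 27 * 2)
})

test_that("prediction intervals follow the closed form and cover new draws", {
  got <- prediction_interval(c(0, 2))
  half <- qt(0.975, df = 1) * sqrt(2) * sqrt(1.5)
  expect_equal(got, c(1 - half, 1 + half), tolerance = 1e-12)
  expect_equal(prediction_interval(rep(3, 5)), c(3, 3))
  expect_error(prediction_interval(1), "at least 2")
  # coverage: a new draw falls inside about 95% of the time at n = 12
  set.seed(19)
  hits <- vapply(1:500, function(i) {
    x <- rnorm(12, 10, 2)
    new <- rnorm(1, 10, 2)
    pi_ <- prediction_interval(x)
    new >= pi_[1] && new <= pi_[2]
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 0.04)
})

test_that("threshold classification treats the boundary as within range", {
  interval <- c(0.1, 0.4)
  expect_equal(exceeds_untreated_range(0.05, interval),
               "improved beyond range")
  expect_equal(exceeds_untreated_range(0.25, interval),
               "within untreated range")
  expect_equal(exceeds_untreated_range(0.1, interval),
               "within untreated range")
})
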