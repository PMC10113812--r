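test_that("the 2-down-1-up rule moves levels as specified", {
  cfg <- staircase_config("two_down_one_up_consecutive", start_level = 65,
                          step = 5, level_bounds = c(30, 90))
  s <- staircase_init(cfg)
  s <- staircase_step(s, TRUE)
  expect_equal(s$level, 65)  # one positive: hold
  s <- staircase_step(s, TRUE)
  expect_equal(s$level, 60)  # two consecutive positives: drop one step
  # counter reset after the change: a single further positive holds
  s <- staircase_step(s, TRUE)
  expect_equal(s$level, 60)
  s <- staircase_step(s, FALSE)
  expect_equal(s$level, 65)  # any negative: rise
  expect_length(s$reversal_levels, 1)  # down then up: one reversal at 60
  expect_equal(s$reversal_levels, 60)
})

test_that("the 3-down-1-up rule requires three consecutive correct responses", {
  cfg <- staircase_config("three_down_one_up_consecutive", start_level = 4,
                          step = 1, level_bounds = c(0.5, 10))
  s <- staircase_init(cfg)
  s <- staircase_step(s, TRUE)
  s <- staircase_step(s, TRUE)
  expect_equal(s$level, 4)   # two correct: hold
  s <- staircase_step(s, FALSE)
  expect_equal(s$level, 5)   # the error resets the run and raises the level
  s <- staircase_step(s, TRUE)
  s <- staircase_step(s, TRUE)
  s <- staircase_step(s, TRUE)
  expect_equal(s$level, 4)   # three consecutive correct: drop
})

test_that("levels clamp at the bounds but reversal logic still sees direction", {
  cfg <- staircase_config("two_down_one_up_consecutive", start_level = 90,
                          step = 5, level_bounds = c(85, 90),
                          stop_reversals = 2, max_trials = 50)
  s <- staircase_init(cfg)
  s <- staircase_step(s, FALSE)  # prescribed increase at the upper bound
  expect_equal(s$level, 90)
  s <- staircase_step(s, TRUE)
  s <- staircase_step(s, TRUE)   # prescribed decrease: direction flip
  expect_equal(s$level, 85)
  expect_length(s$reversal_levels, 1)

  expect_error({
    done <- s
    done$terminated <- TRUE
    staircase_step(done, TRUE)
  }, "terminated")
})

test_that("an always-correct observer never reverses and fails to converge", {
  cfg <- staircase_config("three_down_one_up_consecutive", start_level = 8,
                          step = 1, level_bounds = c(0, 10),
                          stop_reversals = 4, max_trials = 30)
  perfect <- observer_model(threshold_level = -100, spread = 0.1)
  res <- run_staircase(cfg, perfect, seed = 5)
  expect_false(res$converged)
  expect_equal(res$n_trials, 30)
  expect_length(res$reversal_levels, 0)
  expect_true(is.na(res$threshold_estimate))
})

test_that("trajectories stay in bounds, are seed-deterministic, and reversals
           come from visited levels", {
  cfg <- staircase_config("two_down_one_up_consecutive", start_level = 60,
                          step = 5, level_bounds = c(30, 90))
  obs <- observer_model(threshold_level = 55, spread = 4)
  r1 <- run_staircase(cfg, obs, seed = 42)
  r2 <- run_staircase(cfg, obs, seed = 42)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_true(all(r1$trajectory$level >= 30 & r1$trajectory$level <= 90))
  expect_true(all(r1$reversal_levels %in% r1$trajectory$level))
  expect_equal(r1$threshold_estimate, mean(r1$reversal_levels))
})

test_that("staircase estimates bracket the rule's convergence quantiles", {
  # steep observers; mean over seeds should land within one step of the
  # 70.7% (2-down) and 79.4% (3-down) response levels
  obs2 <- observer_model(threshold_level = 62, spread = 1.5)
  cfg2 <- staircase_config("two_down_one_up_consecutive", start_level = 70,
                           step = 5, level_bounds = c(30, 95))
  est2 <- vapply(1:150, function(s) {
    run_staircase(cfg2, obs2, seed = s)$threshold_estimate
  }, numeric(1))
  target2 <- observer_quantile(obs2, 2^(-1 / 2))
  expect_lt(abs(mean(est2) - target2), 5)

  obs3 <- observer_model(threshold_level = 3.5, spread = 0.3)
  cfg3 <- staircase_config("three_down_one_up_consecutive", start_level = 6,
                           step = 1, level_bounds = c(0.25, 10))
  est3 <- vapply(1:150, function(s) {
    run_staircase(cfg3, obs3, seed = s)$threshold_estimate
  }, numeric(1))
  target3 <- observer_quantile(obs3, 2^(-1 / 3))
  expect_lt(abs(mean(est3) - target3), 1)
})

test_that("threshold adjustment factors are exact arithmetic", {
  expect_equal(adjust_threshold(60, phosphene_power_factor), 66)
  expect_equal(adjust_threshold(5.0, orientation_tilt_factor), 6.0)
  expect_equal(adjust_threshold(42.5, 1.0), 42.5)
  expect_error(adjust_threshold(60, -1), "positive")
  expect_error(adjust_threshold(Inf, 1.1), "finite")
})

test_that("observer model probabilities are monotone and bounded", {
  obs <- observer_model(threshold_level = 50, spread = 3,
                        guess_rate = 0.1, lapse_rate = 0.05)
  lv <- seq(30, 70, by = 2)
  p <- observer_prob(obs, lv)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0.1 & p < 0.95))
  expect_equal(observer_prob(obs, observer_quantile(obs, 0.6)), 0.6,
               tolerance = 1e-10)
  expect_error(observer_model(50, 3, guess_rate = 0.6, lapse_rate = 0.5),
               "< 1")
  expect_error(observer_quantile(obs, 0.05), "attainable")
})
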