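test_that("fixed-n design analysis is reproducible and internally coherent", {
  a <- simulate_fixed_n(g = 0, r = 0.58, n = 40, n_sim = 100, seed = 42)
  b <- simulate_fixed_n(g = 0, r = 0.58, n = 40, n_sim = 100, seed = 42)
  expect_identical(a, b)
  expect_equal(a$prop_above_upper + a$prop_below_lower + a$prop_inconclusive,
               1, tolerance = 1e-12)
  expect_true(!is.unsorted(a$bf10_quantiles))

  # extending n_sim preserves the earlier replicates (nested substreams)
  long <- simulate_fixed_n(g = 0, r = 0.58, n = 40, n_sim = 150, seed = 42,
                           keep_replicates = TRUE)
  short <- simulate_fixed_n(g = 0, r = 0.58, n = 40, n_sim = 100, seed = 42,
                            keep_replicates = TRUE)
  expect_equal(attr(long, "replicates")$bf10[1:100],
               attr(short, "replicates")$bf10)

  # unreachable boundaries leave every replicate inconclusive
  open <- simulate_fixed_n(g = 0, r = 0.58, n = 20, n_sim = 50, seed = 1,
                           bf_upper = Inf, bf_lower = 0)
  expect_equal(open$prop_inconclusive, 1)
})

test_that("null-branch boundary proportions order by prior scale", {
  # shared seed gives identical t draws across scales, so the ordering is a
  # property of the Bayes factor itself, not sampling noise
  p <- vapply(c(0.5, 0.58, 0.8), function(r) {
    simulate_fixed_n(g = 0, r = r, n = 40, n_sim = 300,
                     seed = 99)$prop_below_lower
  }, numeric(1))
  expect_true(p[1] < p[2] && p[2] < p[3])
})

test_that("mixture analysis interpolates between its branches", {
  h1 <- hypothesis_spec("alt", g = 0.58, r = 0.58)
  h0 <- hypothesis_spec("null", g = 0, r = 0.58)

  pure_alt <- simulate_mixture(h1, h0, weight = 1, n = 40, n_sim = 300,
                               seed = 3)
  alt_ref <- simulate_fixed_n(g = 0.58, r = 0.58, n = 40, n_sim = 300,
                              seed = 3)
  expect_equal(pure_alt$prop_above_upper, alt_ref$prop_above_upper,
               tolerance = 0.1)

  mix <- simulate_mixture(h1, h0, weight = 0.5, n = 40, n_sim = 400, seed = 4)
  null_ref <- simulate_fixed_n(g = 0, r = 0.58, n = 40, n_sim = 400, seed = 5)
  expected <- (alt_ref$prop_above_upper + alt_ref$prop_below_lower +
                 null_ref$prop_above_upper + null_ref$prop_below_lower) / 2
  combined <- mix$prop_above_upper + mix$prop_below_lower
  expect_equal(combined, expected, tolerance = 0.1)

  expect_error(simulate_mixture(h1, h0, weight = 1.2), "0, 1")
})

test_that("sequential simulation respects the stopping rule mechanics", {
  h <- hypothesis_spec("null", g = 0, r = 0.58)

  # no room to continue
  tight <- design_spec(list(h), n_min = 20, step = 4, n_max = 20)
  res <- simulate_sequential(tight, n_sim = 20, seed = 1)
  expect_equal(unname(res$stopping_n_distribution[["20"]]), 1)

  # unreachable boundaries: every run walks to n_max with terminal "none"
  open <- design_spec(list(h), n_min = 20, step = 4, n_max = 28,
                      bf_upper = 1e9, bf_lower = 1e-9)
  res2 <- simulate_sequential(open, n_sim = 20, seed = 2)
  expect_equal(unname(res2$stopping_n_distribution[["28"]]), 1)
  expect_equal(unname(res2$boundary_proportions$null[["none"]]), 1)

  # three registered-style hypotheses with matching effects stop early
  spec3 <- design_spec(list(hypothesis_spec("H1", 0.58, 0.58),
                            hypothesis_spec("H2", 0.8, 0.8),
                            hypothesis_spec("H3", 0.5, 0.5)))
  res3 <- simulate_sequential(spec3, n_sim = 60, seed = 7)
  expect_lt(res3$mean_stopping_n, 40)
  expect_identical(res3, simulate_sequential(spec3, n_sim = 60, seed = 7))
})

test_that("widening the thresholds never shortens the expected run", {
  h <- hypothesis_spec("weak", g = 0.3, r = 0.58)
  narrow <- design_spec(list(h), bf_upper = 3, bf_lower = 1 / 3)
  wide <- design_spec(list(h), bf_upper = 10, bf_lower = 1 / 10)
  # common random numbers: identical streams under the same seed
  m_narrow <- simulate_sequential(narrow, n_sim = 40, seed = 11)
  m_wide <- simulate_sequential(wide, n_sim = 40, seed = 11)
  expect_gte(m_wide$mean_stopping_n, m_narrow$mean_stopping_n)
})

test_that("evidence trajectories track growing prefixes and surface problems", {
  set.seed(21)
  stream <- rnorm(40, 0.6, 1)
  traj <- evidence_trajectory(stream, r = 0.58, looks = c(10, 20, 30, 40))
  expect_equal(traj$n, c(10, 20, 30, 40))
  ref <- bf10_jzs(t_statistic(stream)$t, 40, 0.58)
  expect_equal(traj$bf10[4], ref$bf10)

  single <- evidence_trajectory(stream, r = 0.58, looks = 40)
  expect_equal(single$bf10, ref$bf10)

  # a degenerate (constant) prefix is reported for that look, then recovers
  mixed <- c(0, 0, 0, rnorm(17, 0.8, 0.5))
  traj2 <- evidence_trajectory(mixed, r = 0.58, looks = c(3, 20))
  expect_true(is.na(traj2$bf10[1]))
  expect_match(traj2$note[1], "degenerate")
  expect_false(is.na(traj2$bf10[2]))

  # a monotone effect stream ends with more evidence than it starts
  grow <- seq(0.1, 1.5, length.out = 30) + rep(c(-0.05, 0.05), 15)
  traj3 <- evidence_trajectory(grow, r = 0.58, looks = c(5, 30))
  expect_gt(traj3$bf10[2], traj3$bf10[1])

  expect_error(evidence_trajectory(stream, 0.58, looks = c(1, 10)), ">= 2")
  expect_error(evidence_trajectory(stream, 0.58, looks = c(10, 50)),
               "stream length")
})
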