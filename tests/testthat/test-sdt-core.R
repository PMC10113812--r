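test_that("participant QC applies the accuracy and data-loss gates", {
  # 310 correct of 432 recorded (71.8%): passes
  ok <- dplyr::bind_rows(
    make_cell_trials(n_signal = 216, hits = 200, n_noise = 216,
                     fas = 106))  # correct = 200 + 110 = 310
  qc <- qc_participant(ok, planned_trials = 432)
  expect_equal(qc$overall_accuracy, 310 / 432, tolerance = 1e-12)
  expect_true(qc$included)
  expect_true(is.na(qc$exclusion_reason))

  # 255 correct of 432 (59.0%): excluded for accuracy
  low <- make_cell_trials(n_signal = 216, hits = 160, n_noise = 216,
                          fas = 121)  # correct = 160 + 95 = 255
  qc_low <- qc_participant(low, planned_trials = 432)
  expect_false(qc_low$included)
  expect_match(qc_low$exclusion_reason, "accuracy below")

  # 340 of 432 planned recorded (21.3% loss): excluded for data loss
  partial <- make_cell_trials(n_signal = 170, hits = 150, n_noise = 170,
                              fas = 30)
  qc_loss <- qc_participant(partial, planned_trials = 432)
  expect_gt(qc_loss$data_loss_fraction, 0.20)
  expect_false(qc_loss$included)
  expect_match(qc_loss$exclusion_reason, "data loss above")

  # boundary is strict: exactly 60% accuracy stays in
  at_60 <- make_cell_trials(n_signal = 50, hits = 30, n_noise = 50, fas = 20)
  expect_true(qc_participant(at_60, planned_trials = 100)$included)

  expect_error(qc_participant(ok[0, ], 432), "non-empty")
})

test_that("no-response trials count as incorrect for QC accuracy", {
  tr <- make_cell_trials(n_signal = 50, hits = 40, none_signal = 10,
                         n_noise = 50, fas = 0, none_noise = 10)
  qc <- qc_participant(tr, planned_trials = 100)
  expect_equal(qc$overall_accuracy, (40 + 40) / 100)
})

test_that("RT filter uses one pass of participant-global 3-sd bounds", {
  base <- make_cell_trials(n_signal = 3, hits = 3, n_noise = 2, fas = 0,
                           rt = c(500, 510, 520, 530, 5000))
  res <- filter_rt(base)
  expect_equal(nrow(res$removed), 0)  # 5000 < mean + 3 sd ~ 7429
  expect_equal(unname(res$bounds["upper"]),
               1412 + 3 * sd(c(500, 510, 520, 530, 5000)), tolerance = 1e-9)

  many <- make_cell_trials(n_signal = 51, hits = 51, n_noise = 50, fas = 0,
                           rt = c(rep(600, 100), 10000))
  res2 <- filter_rt(many)
  expect_equal(nrow(res2$removed), 1)
  expect_equal(res2$removed$rt_ms, 10000)
  expect_lt(unname(res2$bounds["upper"]), 10000)
  expect_equal(nrow(res2$kept) + nrow(res2$removed), nrow(many))

  # all identical: zero-width band keeps everything
  same <- make_cell_trials(rt = 700)
  expect_equal(nrow(filter_rt(same)$removed), 0)

  # no-response trials pass through flagged
  with_none <- make_cell_trials(n_signal = 20, hits = 10, none_signal = 4,
                                n_noise = 20, fas = 5)
  res3 <- filter_rt(with_none)
  expect_equal(sum(res3$kept$rt_exempt), 4)

  two <- make_cell_trials(n_signal = 1, hits = 1, n_noise = 1, fas = 0,
                          none_noise = 1)
  expect_error(filter_rt(two), "fewer than 2 responded")
})

test_that("rate tabulation counts hits and false alarms per the task coding", {
  tr <- make_cell_trials(hits = 27, fas = 9)
  rs <- tabulate_rates(tr, c(tms_site = "ipsilateral", tms_timing_ms = 0))
  expect_equal(rs$hit_rate, 0.75)
  expect_equal(rs$fa_rate, 0.25)
  expect_equal(rs$n_signal, 36)
  expect_equal(rs$n_noise, 36)

  # no-response trials drop from the denominators by default
  tr2 <- make_cell_trials(n_signal = 36, hits = 26, none_signal = 2,
                          n_noise = 36, fas = 9)
  rs2 <- tabulate_rates(tr2, c(tms_site = "ipsilateral"))
  expect_equal(rs2$n_signal, 34)
  expect_equal(rs2$hit_rate, 26 / 34)

  # alternative policy keeps them as "different" responses
  rs3 <- tabulate_rates(tr2, c(tms_site = "ipsilateral"),
                        nonresponse_policy = "count_as_different")
  expect_equal(rs3$n_signal, 36)
  expect_equal(rs3$hit_rate, 26 / 36)

  only_same <- make_cell_trials(n_signal = 20, hits = 15, n_noise = 0,
                                fas = 0)
  expect_error(tabulate_rates(only_same, c(tms_site = "ipsilateral")),
               "degenerate cell")
})

test_that("d-prime matches quantile-oracle values and handles extremes", {
  rs <- tabulate_rates(make_cell_trials(hits = 27, fas = 9),
                       c(tms_site = "ipsilateral"))
  dp <- compute_dprime(rs)
  expect_equal(dp$d_prime, qnorm(0.75) - qnorm(0.25), tolerance = 1e-12)
  expect_equal(dp$d_prime, 1.3490, tolerance = 1e-4)
  expect_false(dp$rates$correction_applied)

  # perfect performance with the half-count clamp: 71/72 vs 1/72
  perfect <- tabulate_rates(make_cell_trials(hits = 36, fas = 0),
                            c(tms_site = "ipsilateral"))
  dpp <- compute_dprime(perfect, correction = "half_count")
  expect_equal(dpp$d_prime, qnorm(71 / 72) - qnorm(1 / 72), tolerance = 1e-12)
  expect_equal(dpp$d_prime, 4.4009, tolerance = 1e-4)
  expect_true(dpp$rates$correction_applied)

  expect_error(compute_dprime(perfect, correction = "none"), "undefined")

  # equal rates give exactly zero sensitivity
  even <- tabulate_rates(make_cell_trials(hits = 12, fas = 12),
                         c(tms_site = "ipsilateral"))
  expect_equal(compute_dprime(even)$d_prime, 0)
})

test_that("d-prime is antisymmetric in H/FA swap and monotone in each rate", {
  make_rs <- function(h, f, n = 40) {
    structure(list(cell = NULL, n_signal = n, n_noise = n,
                   hits = round(h * n), false_alarms = round(f * n),
                   hit_rate = h, fa_rate = f, correction_applied = FALSE),
              class = "rate_summary")
  }
  for (h in c(0.55, 0.75, 0.9)) {
    for (f in c(0.1, 0.25, 0.45)) {
      d <- compute_dprime(make_rs(h, f))$d_prime
      d_swap <- compute_dprime(make_rs(f, h))$d_prime
      expect_equal(d, -d_swap, tolerance = 1e-12)
    }
  }
  hs <- seq(0.05, 0.95, by = 0.05)
  d_by_h <- vapply(hs, function(h) compute_dprime(make_rs(h, 0.2))$d_prime,
                   numeric(1))
  expect_true(all(diff(d_by_h) > 0))
  d_by_f <- vapply(hs, function(f) compute_dprime(make_rs(0.8, f))$d_prime,
                   numeric(1))
  expect_true(all(diff(d_by_f) < 0))
})

test_that("aggregate_dprime covers the design cells and reports gaps", {
  trials <- dplyr::bind_rows(
    make_exp1_participant("P001"),
    make_exp1_participant("P002", hits = rep(30, 6), fas = rep(6, 6)))
  dp <- aggregate_dprime(trials)
  expect_equal(nrow(dp), 12)  # 2 participants x 6 cells
  expect_equal(nrow(attr(dp, "missing_cells")), 0)

  # drop one participant's 1000 ms cells entirely: reported, not imputed
  partial <- trials[!(trials$participant_id == "P002" &
                        trials$tms_timing_ms == 1000), ]
  dp2 <- aggregate_dprime(partial)
  expect_equal(nrow(dp2), 10)
  miss <- attr(dp2, "missing_cells")
  expect_equal(nrow(miss), 2)
  expect_setequal(miss$participant_id, "P002")

  # a degenerate cell propagates with the participant identity attached
  bad <- trials
  bad$trial_type[bad$participant_id == "P001" &
                   bad$tms_timing_ms == 0 &
                   bad$tms_site == "ipsilateral"] <- "same"
  expect_error(aggregate_dprime(bad), "P001")
})
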