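# Independent brute-force oracle for the JZS Bayes factor: fixed-grid
# trapezoid quadrature of the noncentral-t density against the Cauchy prior
# over the standardized effect delta. Deliberately uses the noncentral-t
# route (stats::dt with ncp), a different representation from the package's
# mixture-of-g integrand, so agreement is a genuine cross-check.
bf10_grid_oracle <- function(t, n, r, points = 2e5) {
  delta <- seq(-50 * r, 50 * r, length.out = points)
  f <- suppressWarnings(stats::dt(t, n - 1, ncp = delta * sqrt(n))) *
    stats::dcauchy(delta, 0, r)
  num <- sum((f[-1] + f[-points]) / 2) * (delta[2] - delta[1])
  num / stats::dt(t, n - 1)
}

# Build a trial-table block for one participant x cell with exact response
# counts: n_signal same-probe trials of which `hits` get a "same" response,
# n_noise different-probe trials of which `fas` get a "same" response.
# Optional counts of no-response trials are carved out of the signal/noise
# totals. Reaction times default to a tight band around 600 ms.
make_cell_trials <- function(pid = "P001", experiment = "exp1",
                             tms_site = "ipsilateral", tms_timing_ms = 0,
                             tms_condition = "real",
                             n_signal = 36, hits = 27,
                             n_noise = 36, fas = 9,
                             none_signal = 0, none_noise = 0,
                             rt = 600, block = 1L) {
  n_cw <- floor(n_noise / 2)
  trial_type <- c(rep("same", n_signal),
                  rep("different_cw", n_cw),
                  rep("different_ccw", n_noise - n_cw))
  resp_signal <- c(rep("none", none_signal),
                   rep("same", hits),
                   rep("different", n_signal - none_signal - hits))
  resp_noise <- c(rep("none", none_noise),
                  rep("same", fas),
                  rep("different", n_noise - none_noise - fas))
  response <- c(resp_signal, resp_noise)
  rt_ms <- rep_len(rt, n_signal + n_noise)
  rt_ms[response == "none"] <- NA_real_
  tibble::tibble(
    participant_id = pid, experiment = experiment, block = block,
    tms_site = tms_site, tms_timing_ms = as.integer(tms_timing_ms),
    tms_condition = tms_condition, trial_type = trial_type,
    response = response, rt_ms = rt_ms)
}

# A full experiment-1 participant with chosen hit/fa counts per cell
# (vectors of length 6, cell order ipsi/contra x 0/200/1000).
make_exp1_participant <- function(pid, hits = rep(27, 6), fas = rep(9, 6),
                                  rt = 600) {
  cells <- expand.grid(tms_site = c("ipsilateral", "contralateral"),
                       tms_timing_ms = c(0L, 200L, 1000L),
                       stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    make_cell_trials(pid, "exp1", cells$tms_site[i], cells$tms_timing_ms[i],
                     "real", hits = hits[i], fas = fas[i], rt = rt,
                     block = ((i - 1L) %% 6L) + 1L)
  }))
}
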