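#' @importFrom dplyr %>%
NULL

# canonical column set for a trial table (one row per change-detection trial)
.trial_cols <- c("participant_id", "experiment", "block", "tms_site",
                 "tms_timing_ms", "tms_condition", "trial_type", "response",
                 "rt_ms")

.assert_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0) {
    stop("`trials` must be a non-empty data frame of trial records",
         call. = FALSE)
  }
  missing <- setdiff(.trial_cols, names(trials))
  if (length(missing) > 0) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(trials)
}

.is_correct <- function(trial_type, response) {
  (trial_type == "same" & response == "same") |
    (trial_type %in% c("different_cw", "different_ccw") &
       response == "different")
}

#' Participant-level quality control
#'
#' Applies the study's participant exclusion rules before any trial-level
#' filtering: a participant is excluded when overall accuracy over the
#' recorded experimental trials is strictly below `acc_threshold` (chance-level
#' performance) or when the fraction of planned trials lost (e.g. to technical
#' failure) is strictly above `loss_threshold`. No-response trials count as
#' incorrect (they drew error feedback and encode no decision). Reaction-time
#' summary statistics and the 3-s.d. filter bounds are reported for reference
#' but do not influence inclusion.
#'
#' @param trials Trial table for one participant (all recorded trials).
#' @param planned_trials Number of trials the design planned for this
#'   participant (432 for the 2 x 3 design, 576 for the 2 x 2 x 2 design).
#' @param acc_threshold Accuracy exclusion threshold (default 0.60).
#' @param loss_threshold Data-loss exclusion threshold (default 0.20).
#' @param rt_k Multiplier for the reaction-time filter bounds (default 3).
#' @return A one-row tibble of class `participant_qc` with accuracy, data
#'   loss, RT statistics and bounds, the inclusion flag and, when excluded,
#'   the reason.
#' @export
qc_participant <- function(trials, planned_trials,
                           acc_threshold = 0.60, loss_threshold = 0.20,
                           rt_k = 3) {
  .assert_trials(trials)
  if (!is.numeric(planned_trials) || planned_trials <= 0) {
    stop("`planned_trials` must be a positive count", call. = FALSE)
  }
  n_recorded <- nrow(trials)
  accuracy <- mean(.is_correct(trials$trial_type, trials$response))
  loss <- max(0, 1 - n_recorded / planned_trials)

  responded <- trials$rt_ms[trials$response != "none" & !is.na(trials$rt_ms)]
  if (length(responded) >= 2) {
    m <- mean(responded)
    s <- stats::sd(responded)
    lower <- max(0, m - rt_k * s)
    upper <- m + rt_k * s
    n_removed <- sum(abs(responded - m) > rt_k * s)
  } else {
    m <- s <- lower <- upper <- NA_real_
    n_removed <- NA_integer_
  }

  included <- TRUE
  reason <- NA_character_
  if (accuracy < acc_threshold) {
    included <- FALSE
    reason <- sprintf("accuracy below %.2f", acc_threshold)
  } else if (loss > loss_threshold) {
    included <- FALSE
    reason <- sprintf("data loss above %.2f", loss_threshold)
  }

  out <- tibble::tibble(
    participant_id = as.character(trials$participant_id[[1]]),
    overall_accuracy = accuracy,
    data_loss_fraction = loss,
    rt_mean_ms = m,
    rt_sd_ms = s,
    rt_lower_ms = lower,
    rt_upper_ms = upper,
    n_trials_removed_rt = as.integer(n_removed),
    included = included,
    exclusion_reason = reason
  )
  class(out) <- c("participant_qc", class(out))
  out
}

#' Reaction-time outlier filter
#'
#' Removes trials whose reaction time lies strictly further than `k` sample
#' standard deviations from the participant's mean reaction time. The mean and
#' standard deviation are computed once over all responded trials (a single
#' pass; the bounds are not recomputed after removal, matching a design that
#' reports one exclusion percentage per participant). No-response trials carry
#' no reaction time: they pass through to the kept set untouched, flagged in
#' the `rt_exempt` column.
#'
#' @param trials Trial table for one participant.
#' @param k Standard-deviation multiplier (default 3).
#' @return A list with `kept` and `removed` (a partition of the input rows,
#'   kept rows gaining an `rt_exempt` flag) and `bounds = c(lower, upper)`.
#' @export
filter_rt <- function(trials, k = 3) {
  .assert_trials(trials)
  responded <- trials$response != "none" & !is.na(trials$rt_ms)
  if (sum(responded) < 2) {
    stop("fewer than 2 responded trials: the reaction-time standard ",
         "deviation is undefined", call. = FALSE)
  }
  m <- mean(trials$rt_ms[responded])
  s <- stats::sd(trials$rt_ms[responded])
  out_of_band <- responded & abs(trials$rt_ms - m) > k * s
  kept <- trials[!out_of_band, , drop = FALSE]
  kept$rt_exempt <- kept$response == "none"
  list(
    kept = kept,
    removed = trials[out_of_band, , drop = FALSE],
    bounds = c(lower = m - k * s, upper = m + k * s)
  )
}

.match_cell <- function(trials, cell) {
  sel <- rep(TRUE, nrow(trials))
  for (nm in names(cell)) {
    if (!nm %in% names(trials)) {
      stop("cell key refers to unknown column `", nm, "`", call. = FALSE)
    }
    sel <- sel & (as.character(trials[[nm]]) == as.character(cell[[nm]]))
  }
  sel
}

#' Hit and false-alarm rates for one design cell
#'
#' A hit is a "same" response on a same-probe trial; a false alarm is a "same"
#' response on a different-probe (clockwise or counter-clockwise) trial.
#' No-response trials are handled per `nonresponse_policy`: `"drop"` (default)
#' removes them from both denominators; `"count_as_different"` treats them as
#' "different" responses (never a hit or false alarm, but still counted).
#'
#' @param trials RT-filtered trial table.
#' @param cell Named vector/list selecting the cell, e.g.
#'   `c(tms_site = "ipsilateral", tms_timing_ms = 0)`.
#' @param nonresponse_policy `"drop"` or `"count_as_different"`.
#' @return A list of class `rate_summary`: cell, trial and event counts, raw
#'   rates, and `correction_applied = FALSE` (corrections happen in
#'   [compute_dprime()]).
#' @export
tabulate_rates <- function(trials, cell,
                           nonresponse_policy = c("drop",
                                                  "count_as_different")) {
  .assert_trials(trials)
  nonresponse_policy <- match.arg(nonresponse_policy)
  sub <- trials[.match_cell(trials, cell), , drop = FALSE]
  if (nrow(sub) == 0) {
    stop("cell selects no trials: ",
         paste(names(cell), unlist(cell), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  if (nonresponse_policy == "drop") {
    sub <- sub[sub$response != "none", , drop = FALSE]
  }
  signal <- sub$trial_type == "same"
  noise <- sub$trial_type %in% c("different_cw", "different_ccw")
  n_signal <- sum(signal)
  n_noise <- sum(noise)
  if (n_signal == 0 || n_noise == 0) {
    stop("degenerate cell (",
         paste(names(cell), unlist(cell), sep = "=", collapse = ", "),
         "): no ", if (n_signal == 0) "same" else "different",
         " trials after the no-response policy", call. = FALSE)
  }
  hits <- sum(signal & sub$response == "same")
  fas <- sum(noise & sub$response == "same")
  structure(
    list(
      cell = cell,
      n_signal = n_signal,
      n_noise = n_noise,
      hits = hits,
      false_alarms = fas,
      hit_rate = hits / n_signal,
      fa_rate = fas / n_noise,
      correction_applied = FALSE
    ),
    class = "rate_summary"
  )
}

#' Detection sensitivity d-prime from hit and false-alarm rates
#'
#' Computes d' = z(H) - z(FA), the equal-variance signal-detection sensitivity
#' index, where z is the standard normal quantile function. Rates of exactly 0
#' or 1 make the quantile infinite; with `correction = "half_count"` such
#' extreme rates are replaced by 1/(2n) and 1 - 1/(2n), with n the relevant
#' trial count (the standard extreme-proportion clamp). With
#' `correction = "none"` extreme rates are an error.
#'
#' @param rates A `rate_summary` from [tabulate_rates()].
#' @param correction `"half_count"` (default) or `"none"`.
#' @return A list of class `dprime_result` with `cell`, `d_prime` and the
#'   (possibly corrected) `rates`.
#' @examples
#' r <- structure(list(cell = NULL, n_signal = 36, n_noise = 36, hits = 27,
#'                     false_alarms = 9, hit_rate = 0.75, fa_rate = 0.25,
#'                     correction_applied = FALSE), class = "rate_summary")
#' compute_dprime(r)$d_prime  # 1.349
#' @export
compute_dprime <- function(rates, correction = c("half_count", "none")) {
  if (!inherits(rates, "rate_summary")) {
    stop("`rates` must be a rate_summary from tabulate_rates()",
         call. = FALSE)
  }
  correction <- match.arg(correction)
  h <- rates$hit_rate
  fa <- rates$fa_rate
  if (correction == "none") {
    if (h <= 0 || h >= 1 || fa <= 0 || fa >= 1) {
      stop("hit or false-alarm rate of exactly 0 or 1 with ",
           "correction = \"none\": d-prime is undefined", call. = FALSE)
    }
  } else {
    clamp <- function(p, n) {
      if (p == 0) 1 / (2 * n) else if (p == 1) 1 - 1 / (2 * n) else p
    }
    h_new <- clamp(h, rates$n_signal)
    fa_new <- clamp(fa, rates$n_noise)
    rates$correction_applied <- (h_new != h) || (fa_new != fa)
    h <- h_new
    fa <- fa_new
    rates$hit_rate <- h
    rates$fa_rate <- fa
  }
  structure(
    list(cell = rates$cell,
         d_prime = stats::qnorm(h) - stats::qnorm(fa),
         rates = rates),
    class = "dprime_result"
  )
}

#' Design cells of the two experiments
#'
#' The 2 (site) x 3 (timing) layout of the first experiment (real TMS only)
#' or the 2 (site) x 2 (timing) x 2 (real/sham) layout of the second.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @return A tibble with columns `tms_site`, `tms_timing_ms`, `tms_condition`
#'   (6 rows for exp1, 8 for exp2).
#' @export
design_cells <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    g <- expand.grid(tms_site = c("ipsilateral", "contralateral"),
                     tms_timing_ms = c(0L, 200L, 1000L),
                     tms_condition = "real",
                     stringsAsFactors = FALSE)
  } else {
    g <- expand.grid(tms_site = c("ipsilateral", "contralateral"),
                     tms_timing_ms = c(200L, 1000L),
                     tms_condition = c("real", "sham"),
                     stringsAsFactors = FALSE)
  }
  tibble::as_tibble(g)
}

#' Per-participant, per-cell d-prime table
#'
#' Runs [tabulate_rates()] and [compute_dprime()] for every participant and
#' every design cell of the experiment the trials belong to. Cells a
#' participant is missing entirely are reported in the `missing_cells`
#' attribute, never silently imputed; degenerate cells (no usable signal or
#' noise trials) propagate as errors carrying the participant and cell
#' identity.
#'
#' @param trials RT-filtered trial table (one or more participants, a single
#'   experiment).
#' @param nonresponse_policy Passed to [tabulate_rates()].
#' @param correction Passed to [compute_dprime()].
#' @return A tibble with one row per (participant, cell): the cell columns,
#'   counts, rates and `d_prime`; attribute `missing_cells` lists absent
#'   (participant, cell) combinations.
#' @export
aggregate_dprime <- function(trials,
                             nonresponse_policy = c("drop",
                                                    "count_as_different"),
                             correction = c("half_count", "none")) {
  .assert_trials(trials)
  nonresponse_policy <- match.arg(nonresponse_policy)
  correction <- match.arg(correction)
  experiment <- as.character(trials$experiment[[1]])
  cells <- design_cells(experiment)
  participants <- unique(as.character(trials$participant_id))

  rows <- list()
  missing <- list()
  for (p in participants) {
    ptrials <- trials[as.character(trials$participant_id) == p, , drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      cell <- as.list(cells[i, ])
      if (!any(.match_cell(ptrials, cell))) {
        missing[[length(missing) + 1]] <-
          tibble::tibble(participant_id = p,
                         tms_site = cell$tms_site,
                         tms_timing_ms = cell$tms_timing_ms,
                         tms_condition = cell$tms_condition)
        next
      }
      rs <- tryCatch(
        tabulate_rates(ptrials, cell, nonresponse_policy),
        error = function(e) {
          stop("participant ", p, ": ", conditionMessage(e), call. = FALSE)
        }
      )
      dp <- compute_dprime(rs, correction)
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = p,
        tms_site = cell$tms_site,
        tms_timing_ms = cell$tms_timing_ms,
        tms_condition = cell$tms_condition,
        n_signal = rs$n_signal,
        n_noise = rs$n_noise,
        hits = rs$hits,
        false_alarms = rs$false_alarms,
        hit_rate = dp$rates$hit_rate,
        fa_rate = dp$rates$fa_rate,
        correction_applied = dp$rates$correction_applied,
        d_prime = dp$d_prime
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "missing_cells") <-
    if (length(missing) > 0) dplyr::bind_rows(missing) else
      tibble::tibble(participant_id = character(), tms_site = character(),
                     tms_timing_ms = integer(), tms_condition = character())
  out
}
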