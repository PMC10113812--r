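#' The seven registered hypotheses
#'
#' The preregistered binding of hypothesis to comparison, TMS timing and
#' Cauchy prior scale: three site comparisons (ipsilateral vs contralateral
#' d') for the first experiment at 0 / 200 / 1000 ms with r = 0.58 / 0.8 /
#' 0.5, and for the second experiment the two site comparisons on real-TMS
#' trials (200 ms, r = 0.8; 1000 ms, r = 0.5) plus the two real-vs-sham
#' comparisons across hemispheres at the same timings and scales.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"all"`.
#' @return A tibble with columns `id`, `experiment`, `comparison`
#'   (`"site_ipsi_vs_contra"` or `"condition_real_vs_sham"`), `tms_timing_ms`,
#'   `r`.
#' @export
registered_hypotheses <- function(experiment = c("all", "exp1", "exp2")) {
  experiment <- match.arg(experiment)
  h <- tibble::tibble(
    id = c("H1", "H2", "H3", "H4", "H5", "H6", "H7"),
    experiment = c(rep("exp1", 3), rep("exp2", 4)),
    comparison = c(rep("site_ipsi_vs_contra", 3),
                   "site_ipsi_vs_contra", "condition_real_vs_sham",
                   "site_ipsi_vs_contra", "condition_real_vs_sham"),
    tms_timing_ms = c(0L, 200L, 1000L, 200L, 200L, 1000L, 1000L),
    r = c(0.58, 0.8, 0.5, 0.8, 0.8, 0.5, 0.5)
  )
  if (experiment != "all") h <- h[h$experiment == experiment, ]
  h
}

#' Analysis configuration
#'
#' All thresholds and policies of the registered pipeline in one place; the
#' evidence thresholds appear only here and are applied as strict
#' inequalities.
#'
#' @param acc_threshold,loss_threshold Participant exclusion thresholds.
#' @param rt_k Reaction-time filter multiplier.
#' @param nonresponse_policy,correction Passed to the d' stage.
#' @param bf_upper,bf_lower Evidence thresholds.
#' @param hemisphere_pooling For the real-vs-sham comparisons:
#'   `"average_dprime"` (default) averages each participant's ipsilateral and
#'   contralateral cell d' within a stimulation condition before differencing;
#'   `"pool_trials"` pools the trials of both sites and computes one d' per
#'   condition.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(acc_threshold = 0.60, loss_threshold = 0.20,
                            rt_k = 3,
                            nonresponse_policy = c("drop",
                                                   "count_as_different"),
                            correction = c("half_count", "none"),
                            bf_upper = 3, bf_lower = 1 / 3,
                            hemisphere_pooling = c("average_dprime",
                                                   "pool_trials")) {
  structure(list(
    acc_threshold = acc_threshold,
    loss_threshold = loss_threshold,
    rt_k = rt_k,
    nonresponse_policy = match.arg(nonresponse_policy),
    correction = match.arg(correction),
    bf_upper = bf_upper,
    bf_lower = bf_lower,
    hemisphere_pooling = match.arg(hemisphere_pooling)
  ), class = "analysis_config")
}

.bf_decision <- function(bf10, upper, lower) {
  if (is.na(bf10)) return(NA_character_)
  if (bf10 > upper) "supports_H1" else if (bf10 < lower) "supports_H0" else
    "inconclusive"
}

# per-participant paired difference for one hypothesis, from the cell-level
# d-prime table (dp) and, for pool_trials, the filtered trials
.hypothesis_differences <- function(hyp, dp, trials, config) {
  timing <- hyp$tms_timing_ms
  if (hyp$comparison == "site_ipsi_vs_contra") {
    sub <- dp[dp$tms_timing_ms == timing & dp$tms_condition == "real", ]
    wide <- split(sub, sub$participant_id)
    vals <- vapply(wide, function(w) {
      i <- w$d_prime[w$tms_site == "ipsilateral"]
      c <- w$d_prime[w$tms_site == "contralateral"]
      if (length(i) == 1 && length(c) == 1) i - c else NA_real_
    }, numeric(1))
  } else if (config$hemisphere_pooling == "average_dprime") {
    sub <- dp[dp$tms_timing_ms == timing, ]
    wide <- split(sub, sub$participant_id)
    vals <- vapply(wide, function(w) {
      real <- w$d_prime[w$tms_condition == "real"]
      sham <- w$d_prime[w$tms_condition == "sham"]
      if (length(real) == 2 && length(sham) == 2) {
        mean(real) - mean(sham)
      } else NA_real_
    }, numeric(1))
  } else {
    # pool trials across sites within condition, one d' per condition
    vals <- vapply(split(trials, as.character(trials$participant_id)),
                   function(tr) {
      d_cond <- vapply(c("real", "sham"), function(cond) {
        sel <- c(tms_timing_ms = timing, tms_condition = cond)
        out <- tryCatch({
          rs <- tabulate_rates(tr, sel, config$nonresponse_policy)
          compute_dprime(rs, config$correction)$d_prime
        }, error = function(e) NA_real_)
        out
      }, numeric(1))
      d_cond[["real"]] - d_cond[["sham"]]
    }, numeric(1))
  }
  vals[!is.na(vals)]
}

#' Run the registered analysis end-to-end
#'
#' Trial table in, analysis report out: participant quality control (accuracy
#' and data-loss gates), per-participant reaction-time filtering, the
#' per-cell d' table, then the experiment's registered Bayesian paired
#' t-tests with prior-width robustness curves and a three-way decision per
#' hypothesis at the strict 3 / (1/3) thresholds. Sham trials are excluded
#' from the site comparisons of the second experiment; the real-vs-sham
#' comparisons average d' across hemispheres within condition (configurable).
#' A hypothesis whose differences are degenerate (zero variance) or whose
#' cells are absent is reported as not computable, with the reason, never
#' silently dropped.
#'
#' @param trials Trial table (one experiment).
#' @param config An [analysis_config()].
#' @param planned_trials Planned trials per participant; defaults to 432
#'   (exp1) or 576 (exp2).
#' @return A list of class `analysis_report`: `experiment`, `qc`,
#'   `excluded`, `dprime`, `missing_cells`, `hypotheses` (id, comparison,
#'   timing, r, n, t, bf10, log_bf10, decision, note), `robustness` (named
#'   list of curves), `config` and a deterministic `fingerprint`.
#' @export
run_registered_analysis <- function(trials, config = analysis_config(),
                                    planned_trials = NULL) {
  .assert_trials(trials)
  stopifnot(inherits(config, "analysis_config"))
  experiment <- as.character(trials$experiment[[1]])
  if (is.null(planned_trials)) {
    planned_trials <- if (experiment == "exp1") 432L else 576L
  }

  by_participant <- split(trials, as.character(trials$participant_id))
  qc <- dplyr::bind_rows(lapply(by_participant, qc_participant,
                                planned_trials = planned_trials,
                                acc_threshold = config$acc_threshold,
                                loss_threshold = config$loss_threshold,
                                rt_k = config$rt_k))
  included_ids <- qc$participant_id[qc$included]
  if (length(included_ids) < 2) {
    stop("fewer than 2 participants pass quality control", call. = FALSE)
  }
  filtered <- dplyr::bind_rows(lapply(by_participant[included_ids],
                                      function(tr) filter_rt(tr,
                                                             config$rt_k)$kept))
  filtered$rt_exempt <- NULL

  dp <- aggregate_dprime(filtered,
                         nonresponse_policy = config$nonresponse_policy,
                         correction = config$correction)

  hyps <- registered_hypotheses(experiment)
  rob <- list()
  rows <- lapply(seq_len(nrow(hyps)), function(i) {
    hyp <- as.list(hyps[i, ])
    diffs <- .hypothesis_differences(hyp, dp, filtered, config)
    row <- tibble::tibble(id = hyp$id, experiment = hyp$experiment,
                          comparison = hyp$comparison,
                          tms_timing_ms = hyp$tms_timing_ms, r = hyp$r,
                          n = length(diffs), mean_difference = NA_real_,
                          t = NA_real_, bf10 = NA_real_,
                          log_bf10 = NA_real_, decision = NA_character_,
                          note = NA_character_)
    if (length(diffs) < 2) {
      row$note <- "not computable: fewer than 2 participants with both cells"
      return(row)
    }
    res <- tryCatch({
      ts <- t_statistic(diffs)
      bf <- bf10_jzs(ts$t, ts$n, hyp$r)
      rob[[hyp$id]] <<- bf_robustness(ts$t, ts$n, hyp$r)
      row$mean_difference <- mean(diffs)
      row$t <- bf$t
      row$bf10 <- bf$bf10
      row$log_bf10 <- bf$log_bf10
      row$decision <- .bf_decision(bf$bf10, config$bf_upper, config$bf_lower)
      row
    }, error = function(e) {
      row$note <- paste0("degenerate data: ", conditionMessage(e))
      row
    })
    res
  })

  structure(
    list(experiment = experiment,
         qc = qc,
         excluded = qc[!qc$included, , drop = FALSE],
         dprime = dp,
         missing_cells = attr(dp, "missing_cells"),
         hypotheses = dplyr::bind_rows(rows),
         robustness = rob,
         config = config,
         fingerprint = .report_fingerprint(config)),
    class = "analysis_report"
  )
}

.report_fingerprint <- function(config) {
  paste0("vstmtms ", as.character(utils::packageVersion("vstmtms")), " | ",
         jsonlite::toJSON(unclass(config), auto_unbox = TRUE))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Registered analysis report (%s): %d included / %d excluded participants\n",
              x$experiment, sum(x$qc$included), sum(!x$qc$included)))
  print(as.data.frame(
    x$hypotheses[, c("id", "tms_timing_ms", "r", "n", "t", "bf10",
                     "decision")]), digits = 4)
  invisible(x)
}

#' Mean and s.d. of d' per design cell
#'
#' Condition-level summary of an analysis report's d' table, the shape of the
#' published summary tables (cell, mean (s.d.) d').
#'
#' @param report An `analysis_report`.
#' @return A tibble with one row per cell: mean, s.d. and n of participant d'.
#' @export
condition_summary <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  dplyr::summarise(
    dplyr::group_by(report$dprime, .data$tms_site, .data$tms_timing_ms,
                    .data$tms_condition),
    mean_d_prime = mean(.data$d_prime),
    sd_d_prime = stats::sd(.data$d_prime),
    n = dplyr::n(),
    .groups = "drop")
}

#' Sequential monitoring of accumulating participants
#'
#' Replays the registered sample-updating procedure on a trial table:
#' participants are taken in arrival order (order of first appearance), and at
#' each look (n = `n_min`, `n_min + step`, ... up to `n_max`) the full
#' registered analysis runs on the accumulated participants. The stopping
#' rule is met at the first look where every computable hypothesis's Bayes
#' factor lies strictly outside (`bf_lower`, `bf_upper`).
#'
#' @param trials Trial table with participants in arrival order.
#' @param config An [analysis_config()].
#' @param n_min,step,n_max The sampling plan (defaults 20 / 4 / 40).
#' @return A list of class `sequential_log`: `looks` (tibble of look_n,
#'   hypothesis id, bf10, decision, stop_met), `stopped_at` (first satisfying
#'   look, or NA), `note`.
#' @export
sequential_monitor <- function(trials, config = analysis_config(),
                               n_min = 20, step = 4, n_max = 40) {
  .assert_trials(trials)
  ids <- unique(as.character(trials$participant_id))
  if (length(ids) < n_min) {
    return(structure(list(
      looks = tibble::tibble(), stopped_at = NA_integer_,
      note = sprintf("insufficient for first look: %d participants < n_min = %d",
                     length(ids), n_min)),
      class = "sequential_log"))
  }
  looks <- seq(n_min, min(n_max, length(ids)), by = step)
  log_rows <- list()
  stopped_at <- NA_integer_
  for (n in looks) {
    sub <- trials[as.character(trials$participant_id) %in% ids[seq_len(n)], ,
                  drop = FALSE]
    rep_n <- run_registered_analysis(sub, config)
    h <- rep_n$hypotheses
    computable <- !is.na(h$bf10)
    stop_met <- length(computable) > 0 && all(computable) &&
      all(h$bf10 > config$bf_upper | h$bf10 < config$bf_lower)
    log_rows[[length(log_rows) + 1]] <- tibble::tibble(
      look_n = n, id = h$id, bf10 = h$bf10, decision = h$decision,
      stop_met = stop_met)
    if (stop_met && is.na(stopped_at)) {
      stopped_at <- n
      break
    }
  }
  structure(
    list(looks = dplyr::bind_rows(log_rows),
         stopped_at = stopped_at,
         note = if (is.na(stopped_at))
           "stopped at n_max without full satisfaction" else
             sprintf("stopping rule met at n = %d", stopped_at)),
    class = "sequential_log"
  )
}

#' Write an analysis report to disk
#'
#' Serializes the report deterministically: the QC table, per-cell d' table
#' and hypothesis table as comma-separated text, and the full report
#' (including robustness curves, configuration and fingerprint) as JSON keyed
#' by participant and hypothesis.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    qc = file.path(dir, "participant_qc.csv"),
    dprime = file.path(dir, "dprime_by_cell.csv"),
    hypotheses = file.path(dir, "hypothesis_bfs.csv"),
    report = file.path(dir, "report.json")
  )
  readr::write_csv(report$qc, paths[["qc"]], na = "")
  readr::write_csv(report$dprime, paths[["dprime"]], na = "")
  readr::write_csv(report$hypotheses, paths[["hypotheses"]], na = "")
  jsonlite::write_json(
    list(experiment = report$experiment,
         fingerprint = report$fingerprint,
         config = unclass(report$config),
         qc = report$qc,
         dprime = report$dprime,
         missing_cells = report$missing_cells,
         hypotheses = report$hypotheses,
         robustness = report$robustness),
    paths[["report"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
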