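#' Hit and false-alarm probabilities of an equal-variance observer
#'
#' Inverts the d' definition under the equal-variance Gaussian observer with
#' decision criterion c (in quantile units): hit_p = Phi(d'/2 - c),
#' fa_p = Phi(-d'/2 - c). Feeding the exact rates back through
#' z(hit_p) - z(fa_p) recovers d' identically.
#'
#' @param d_prime True sensitivity (vectorized).
#' @param criterion Decision bias c; 0 is unbiased, positive is conservative
#'   (fewer "same" responses).
#' @return A list with numeric vectors `hit_p` and `fa_p`.
#' @examples
#' rates_from_dprime(1.3490, 0)  # ~ (0.75, 0.25)
#' @export
rates_from_dprime <- function(d_prime, criterion = 0) {
  list(hit_p = stats::pnorm(d_prime / 2 - criterion),
       fa_p = stats::pnorm(-d_prime / 2 - criterion))
}

#' Condition-cell specification for the generator
#'
#' @param tms_site `"ipsilateral"` or `"contralateral"`.
#' @param tms_timing_ms TMS timing (0, 200 or 1000).
#' @param tms_condition `"real"` or `"sham"`.
#' @param true_d_prime Population-mean sensitivity in the cell.
#' @param criterion Decision criterion (quantile units).
#' @param n_trials Trials in the cell (even; half same-probe, a quarter each
#'   clockwise / counter-clockwise changed; default 72).
#' @return A list of class `cell_spec`.
#' @export
cell_spec <- function(tms_site, tms_timing_ms, tms_condition = "real",
                      true_d_prime, criterion = 0, n_trials = 72) {
  if (n_trials %% 2 != 0) stop("`n_trials` must be even", call. = FALSE)
  structure(list(tms_site = tms_site,
                 tms_timing_ms = as.integer(tms_timing_ms),
                 tms_condition = tms_condition,
                 true_d_prime = true_d_prime,
                 criterion = criterion,
                 n_trials = as.integer(n_trials)),
            class = "cell_spec")
}

#' Population specification for a synthetic experiment
#'
#' Describes the generative model the analysis assumes: per-cell
#' population-mean sensitivity with correlated participant-level deviations,
#' a lognormal reaction-time model with injectable outliers truncated at the
#' 3000 ms response window, and a nonresponse probability.
#'
#' @param experiment `"exp1"` (2 sites x 3 timings) or `"exp2"`
#'   (2 x 2 x 2 with sham).
#' @param cell_specs List of [cell_spec()] (6 for exp1, 8 for exp2).
#' @param n_participants Number of participants to generate.
#' @param between_sd Between-participant s.d. of cell-level d' deviations.
#' @param cross_corr Correlation of a participant's deviations across cells.
#' @param rt_meanlog,rt_sdlog Lognormal reaction-time parameters (ms scale).
#' @param rt_outlier_prob,rt_outlier_factor Probability and multiplicative
#'   magnitude of injected slow-response outliers.
#' @param nonresponse_prob Probability a trial times out with no response.
#' @param seed Master seed; all generation is deterministic given it.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(experiment, cell_specs, n_participants,
                            between_sd = 0.65, cross_corr = 0.7,
                            rt_meanlog = log(700), rt_sdlog = 0.3,
                            rt_outlier_prob = 0.035, rt_outlier_factor = 10,
                            nonresponse_prob = 0.01, seed = 1) {
  experiment <- match.arg(experiment, c("exp1", "exp2"))
  stopifnot(all(vapply(cell_specs, inherits, TRUE, "cell_spec")))
  expected <- if (experiment == "exp1") 6L else 8L
  if (length(cell_specs) != expected) {
    stop("`", experiment, "` needs ", expected, " cell specs", call. = FALSE)
  }
  if (between_sd < 0) stop("`between_sd` must be >= 0", call. = FALSE)
  if (abs(cross_corr) > 1) stop("`cross_corr` must be in [-1, 1]",
                                call. = FALSE)
  if (rt_outlier_prob < 0 || rt_outlier_prob > 1 ||
      nonresponse_prob < 0 || nonresponse_prob > 1) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  structure(list(experiment = experiment, cell_specs = cell_specs,
                 n_participants = as.integer(n_participants),
                 between_sd = between_sd, cross_corr = cross_corr,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rt_outlier_prob = rt_outlier_prob,
                 rt_outlier_factor = rt_outlier_factor,
                 nonresponse_prob = nonresponse_prob,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Default population for the 2 x 3 (site x timing) experiment
#'
#' Cell means default to the reported condition means of the first
#' experiment's registered analyses (ipsilateral 0.95 / 1.11 / 0.99 and
#' contralateral 1.56 / 1.65 / 1.45 at 0 / 200 / 1000 ms).
#'
#' @param n_participants Default 36, the achieved sample.
#' @param true_d_prime Named list/vector of six cell means in the order
#'   ipsi 0, contra 0, ipsi 200, contra 200, ipsi 1000, contra 1000.
#' @param ... Passed to [population_spec()].
#' @export
exp1_population <- function(n_participants = 36,
                            true_d_prime = c(0.95, 1.56, 1.11, 1.65,
                                             0.99, 1.45),
                            ...) {
  grid <- expand.grid(tms_site = c("ipsilateral", "contralateral"),
                      tms_timing_ms = c(0L, 200L, 1000L),
                      stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    cell_spec(grid$tms_site[i], grid$tms_timing_ms[i], "real",
              true_d_prime[i])
  })
  population_spec("exp1", cells, n_participants, ...)
}

#' Default population for the 2 x 2 x 2 (site x timing x real/sham) experiment
#'
#' Real-TMS cell means default to the second experiment's reported site
#' comparison means (ipsilateral 0.72 / 0.85, contralateral 1.66 / 1.59 at
#' 200 / 1000 ms); sham cells default to the reported sham condition means
#' (ipsilateral 1.05 / 1.14, contralateral 1.76 / 1.76).
#'
#' @param n_participants Default 28, the achieved sample.
#' @param true_d_prime Eight cell means in the order ipsi/contra x 200/1000 x
#'   real/sham.
#' @param ... Passed to [population_spec()].
#' @export
exp2_population <- function(n_participants = 28,
                            true_d_prime = c(0.72, 1.66, 0.85, 1.59,
                                             1.05, 1.76, 1.14, 1.76),
                            ...) {
  grid <- expand.grid(tms_site = c("ipsilateral", "contralateral"),
                      tms_timing_ms = c(200L, 1000L),
                      tms_condition = c("real", "sham"),
                      stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    cell_spec(grid$tms_site[i], grid$tms_timing_ms[i], grid$tms_condition[i],
              true_d_prime[i])
  })
  population_spec("exp2", cells, n_participants, ...)
}

# correlated participant-level d-prime deviations across cells
.participant_deviations <- function(pop) {
  k <- length(pop$cell_specs)
  if (pop$between_sd == 0) return(rep(0, k))
  sigma <- pop$between_sd^2 *
    ((1 - pop$cross_corr) * diag(k) + pop$cross_corr * matrix(1, k, k))
  drop(MASS::mvrnorm(1, mu = rep(0, k), Sigma = sigma))
}

#' Generate one participant's trials
#'
#' Draws the participant's per-cell sensitivity (cell mean plus correlated
#' deviation), converts it to hit/false-alarm probabilities via
#' [rates_from_dprime()] (probabilities are clamped into (0, 1) with a warning
#' if a deviation makes a cell infeasible), samples Bernoulli responses,
#' reaction times from the truncated lognormal model with outlier injection,
#' and stamps nonresponse trials. Trial order is shuffled and split into
#' 72-trial blocks, all deterministically from the population seed and
#' participant index.
#'
#' @param pop A [population_spec()].
#' @param participant_index 1-based index < = `n_participants`.
#' @return A list with `trials` (a trial-table tibble) and `truth` (per-cell
#'   realized d', probabilities, injected outlier and nonresponse counts).
#' @export
generate_participant <- function(pop, participant_index) {
  stopifnot(inherits(pop, "population_spec"))
  if (participant_index < 1 || participant_index > pop$n_participants) {
    stop("`participant_index` out of range", call. = FALSE)
  }
  pid <- sprintf("P%03d", participant_index)
  sub_seed <- .substream_seed(pop$seed, participant_index)

  withr::with_seed(sub_seed, {
    dev <- .participant_deviations(pop)
    cell_rows <- list()
    truth_rows <- list()
    for (j in seq_along(pop$cell_specs)) {
      cs <- pop$cell_specs[[j]]
      d_j <- cs$true_d_prime + dev[j]
      pr <- rates_from_dprime(d_j, cs$criterion)
      eps <- 1e-4
      clamped <- pr$hit_p < eps || pr$hit_p > 1 - eps ||
        pr$fa_p < eps || pr$fa_p > 1 - eps
      if (clamped) {
        warning("participant ", pid, " cell ", cs$tms_site, "/",
                cs$tms_timing_ms, "/", cs$tms_condition,
                ": infeasible response probability clamped", call. = FALSE)
      }
      hit_p <- min(max(pr$hit_p, eps), 1 - eps)
      fa_p <- min(max(pr$fa_p, eps), 1 - eps)

      n_half <- cs$n_trials / 2
      n_q <- floor(n_half / 2)
      trial_type <- c(rep("same", n_half),
                      rep("different_cw", n_q),
                      rep("different_ccw", n_half - n_q))
      is_signal <- trial_type == "same"
      p_same <- ifelse(is_signal, hit_p, fa_p)
      response <- ifelse(stats::runif(cs$n_trials) < p_same,
                         "same", "different")

      rt <- stats::rlnorm(cs$n_trials, pop$rt_meanlog, pop$rt_sdlog)
      outlier <- stats::runif(cs$n_trials) < pop$rt_outlier_prob
      rt[outlier] <- rt[outlier] * pop$rt_outlier_factor
      rt <- pmin(rt, 3000)
      nonresp <- stats::runif(cs$n_trials) < pop$nonresponse_prob
      response[nonresp] <- "none"
      rt[nonresp] <- NA_real_

      cell_rows[[j]] <- tibble::tibble(
        participant_id = pid,
        experiment = pop$experiment,
        tms_site = cs$tms_site,
        tms_timing_ms = cs$tms_timing_ms,
        tms_condition = cs$tms_condition,
        trial_type = trial_type,
        response = response,
        rt_ms = rt
      )
      truth_rows[[j]] <- tibble::tibble(
        participant_id = pid,
        tms_site = cs$tms_site,
        tms_timing_ms = cs$tms_timing_ms,
        tms_condition = cs$tms_condition,
        true_d_prime_cell = cs$true_d_prime,
        true_d_prime_participant = d_j,
        criterion = cs$criterion,
        hit_p = hit_p,
        fa_p = fa_p,
        clamped = clamped,
        n_outliers_injected = sum(outlier & !nonresp),
        n_nonresponse = sum(nonresp)
      )
    }
    trials <- dplyr::bind_rows(cell_rows)
    perm <- sample.int(nrow(trials))
    trials <- trials[perm, , drop = FALSE]
    trials$block <- rep(seq_len(ceiling(nrow(trials) / 72)),
                        each = 72)[seq_len(nrow(trials))]
    trials <- trials[, .trial_cols]
    list(trials = trials, truth = dplyr::bind_rows(truth_rows))
  })
}

#' Generate a full synthetic experiment with ground truth
#'
#' @param pop A [population_spec()].
#' @return A list of class `synthetic_experiment` with `trials` (all
#'   participants' trial table), `truth` (per-participant, per-cell realized
#'   parameters) and `pop` (the generating specification). Two calls with the
#'   same specification are identical.
#' @export
generate_experiment <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  if (pop$n_participants == 0) {
    empty <- tibble::tibble(
      participant_id = character(), experiment = character(),
      block = integer(), tms_site = character(), tms_timing_ms = integer(),
      tms_condition = character(), trial_type = character(),
      response = character(), rt_ms = numeric())
    return(structure(list(trials = empty, truth = tibble::tibble(),
                          pop = pop),
                     class = "synthetic_experiment"))
  }
  parts <- lapply(seq_len(pop$n_participants),
                  function(i) generate_participant(pop, i))
  structure(
    list(trials = dplyr::bind_rows(lapply(parts, `[[`, "trials")),
         truth = dplyr::bind_rows(lapply(parts, `[[`, "truth")),
         pop = pop),
    class = "synthetic_experiment"
  )
}

#' Write a synthetic experiment to disk
#'
#' Writes the trial table as comma-separated text (missing reaction times as
#' empty fields) and the ground truth plus generating parameters as a JSON
#' sidecar, sufficient to recompute every generated quantity.
#'
#' @param x A `synthetic_experiment`.
#' @param dir Output directory (created if absent).
#' @param stem File stem (default the experiment label).
#' @return Invisibly, the two file paths.
#' @export
write_experiment <- function(x, dir, stem = x$pop$experiment) {
  stopifnot(inherits(x, "synthetic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trial_path <- file.path(dir, paste0(stem, "_trials.csv"))
  truth_path <- file.path(dir, paste0(stem, "_truth.json"))
  readr::write_csv(x$trials, trial_path, na = "")
  pop_flat <- x$pop
  pop_flat$cell_specs <- lapply(pop_flat$cell_specs, unclass)
  jsonlite::write_json(
    list(pop = unclass(pop_flat), truth = x$truth),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(trials = trial_path, truth = truth_path))
}

#' Read a trial table written by [write_experiment()]
#'
#' @param path CSV path with the canonical trial-record header.
#' @return A validated trial-table tibble (empty `rt_ms` fields become `NA`).
#' @export
read_trial_table <- function(path) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      experiment = readr::col_character(),
      block = readr::col_integer(),
      tms_site = readr::col_character(),
      tms_timing_ms = readr::col_integer(),
      tms_condition = readr::col_character(),
      trial_type = readr::col_character(),
      response = readr::col_character(),
      rt_ms = readr::col_double()
    ),
    na = c("", "NA"))
  .assert_trials(trials)
  trials
}
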