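#' Simulated psychometric observer
#'
#' Stands in for a human observer in staircase simulations: the probability of
#' a positive response (seeing a phosphene, a correct orientation judgement)
#' rises with stimulus level following a logistic or cumulative-normal
#' psychometric function, bounded below by a guess rate and above by
#' 1 - lapse rate.
#'
#' @param threshold_level Level of the family's 50% point (before guess/lapse
#'   scaling): stimulator output in percentage points, or tilt in degrees.
#' @param spread Positive scale of the psychometric function (smaller =
#'   steeper); the logistic uses `plogis((level - threshold)/spread)`, the
#'   cumulative normal `pnorm(...)`.
#' @param family `"logistic"` or `"cumulative_normal"`.
#' @param lapse_rate,guess_rate Proportions in [0, 1), summing below 1.
#' @return A list of class `observer_model`.
#' @export
observer_model <- function(threshold_level, spread,
                           family = c("logistic", "cumulative_normal"),
                           lapse_rate = 0, guess_rate = 0) {
  family <- match.arg(family)
  if (spread <= 0) stop("`spread` must be > 0", call. = FALSE)
  if (guess_rate + lapse_rate >= 1) {
    stop("guess_rate + lapse_rate must be < 1", call. = FALSE)
  }
  structure(list(family = family, threshold_level = threshold_level,
                 spread = spread, lapse_rate = lapse_rate,
                 guess_rate = guess_rate),
            class = "observer_model")
}

#' Positive-response probability of an observer at a level
#' @param observer An [observer_model()].
#' @param level Stimulus level(s).
#' @return Probability (vectorized over `level`).
#' @export
observer_prob <- function(observer, level) {
  stopifnot(inherits(observer, "observer_model"))
  z <- (level - observer$threshold_level) / observer$spread
  base <- if (observer$family == "logistic") stats::plogis(z) else
    stats::pnorm(z)
  observer$guess_rate + (1 - observer$guess_rate - observer$lapse_rate) * base
}

#' Level at which an observer reaches a given response probability
#' @param observer An [observer_model()].
#' @param p Target total response probability (must lie strictly between the
#'   guess rate and 1 - lapse rate).
#' @return The stimulus level.
#' @export
observer_quantile <- function(observer, p) {
  stopifnot(inherits(observer, "observer_model"))
  base <- (p - observer$guess_rate) /
    (1 - observer$guess_rate - observer$lapse_rate)
  if (base <= 0 || base >= 1) {
    stop("`p` is outside the observer's attainable range", call. = FALSE)
  }
  z <- if (observer$family == "logistic") stats::qlogis(base) else
    stats::qnorm(base)
  observer$threshold_level + observer$spread * z
}

#' Staircase configuration
#'
#' The two transformed up-down rules used for threshold estimation:
#' `"two_down_one_up_consecutive"` (phosphene threshold on stimulator output:
#' level drops after two consecutive positive reports at the same level, rises
#' after every negative) and `"three_down_one_up_consecutive"` (orientation
#' discrimination: tilt drops after three consecutive correct responses, rises
#' on any error). These rules converge towards the 70.7% and 79.4% response
#' levels respectively (0.5^(1/2) and 0.5^(1/3)).
#'
#' @param rule One of the two rule names.
#' @param start_level Starting level, inside `level_bounds`.
#' @param step Positive step size (default 5 percentage points of stimulator
#'   output for the 2-down rule, 1 degree for the 3-down rule would be typical).
#' @param level_bounds Length-2 numeric: the levels are clamped to this range.
#' @param stop_reversals Reversals required to terminate (>= 2, default 8).
#' @param max_trials Hard trial cap (default 200).
#' @return A list of class `staircase_config`.
#' @export
staircase_config <- function(rule = c("two_down_one_up_consecutive",
                                      "three_down_one_up_consecutive"),
                             start_level, step, level_bounds,
                             stop_reversals = 8, max_trials = 200) {
  rule <- match.arg(rule)
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (stop_reversals < 2) stop("`stop_reversals` must be >= 2", call. = FALSE)
  if (start_level < level_bounds[1] || start_level > level_bounds[2]) {
    stop("`start_level` must lie within `level_bounds`", call. = FALSE)
  }
  structure(list(rule = rule, start_level = start_level, step = step,
                 level_bounds = level_bounds, stop_reversals = stop_reversals,
                 max_trials = max_trials),
            class = "staircase_config")
}

#' Initialize a staircase run state
#' @param config A [staircase_config()].
#' @return A `staircase_state` ready for [staircase_step()].
#' @export
staircase_init <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(
    list(config = config,
         level = config$start_level,
         consecutive = 0L,          # consecutive positives at current level
         last_change = 0,           # sign of previous prescribed change
         reversal_levels = numeric(0),
         trajectory = list(),
         trial = 0L,
         terminated = FALSE),
    class = "staircase_state"
  )
}

#' Advance a staircase by one trial
#'
#' Applies the configured up-down rule to one observer response. For the
#' k-down-1-up consecutive rules, the level decreases by one step only after k
#' consecutive positive responses at the same level (the counter resets on any
#' level change and on any negative response) and increases by one step after
#' every negative response. A reversal is recorded when the prescribed level
#' change has the opposite sign to the previous nonzero prescribed change;
#' levels are clamped to the configured bounds but the prescribed direction
#' still drives reversal logic at a bound.
#'
#' @param state A `staircase_state`.
#' @param response Logical: positive report / correct response.
#' @return The updated `staircase_state`; `$terminated` becomes TRUE when the
#'   reversal target or the trial cap is reached.
#' @export
staircase_step <- function(state, response) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$terminated) {
    stop("staircase run already terminated", call. = FALSE)
  }
  if (!is.logical(response) || length(response) != 1 || is.na(response)) {
    stop("`response` must be a single TRUE/FALSE", call. = FALSE)
  }
  cfg <- state$config
  k_down <- if (cfg$rule == "two_down_one_up_consecutive") 2L else 3L

  state$trial <- state$trial + 1L
  state$trajectory[[state$trial]] <-
    list(trial = state$trial, level = state$level, response = response)

  change <- 0
  if (response) {
    state$consecutive <- state$consecutive + 1L
    if (state$consecutive >= k_down) {
      change <- -1
      state$consecutive <- 0L
    }
  } else {
    change <- +1
    state$consecutive <- 0L
  }

  if (change != 0) {
    # reversal: prescribed direction flips relative to the last nonzero change
    if (state$last_change != 0 && change != state$last_change) {
      state$reversal_levels <- c(state$reversal_levels, state$level)
    }
    state$last_change <- change
    state$level <- min(max(state$level + change * cfg$step,
                           cfg$level_bounds[1]), cfg$level_bounds[2])
  }

  if (length(state$reversal_levels) >= cfg$stop_reversals ||
      state$trial >= cfg$max_trials) {
    state$terminated <- TRUE
  }
  state
}

#' Run a full staircase against a simulated observer
#'
#' Iterates [staircase_step()] with Bernoulli responses drawn from the
#' observer's psychometric function until the reversal target or the trial cap
#' is hit. The threshold estimate is the arithmetic mean of the reversal
#' levels (the mean of the levels where the run changed direction).
#'
#' @param config A [staircase_config()].
#' @param observer An [observer_model()].
#' @param seed Integer seed; the same seed reproduces the trajectory exactly.
#' @return A list of class `staircase_result`: `trajectory` tibble (trial,
#'   level, response), `reversal_levels`, `threshold_estimate`, `converged`
#'   (TRUE iff the reversal target was reached), `n_trials`.
#' @export
run_staircase <- function(config, observer, seed = 1) {
  stopifnot(inherits(config, "staircase_config"),
            inherits(observer, "observer_model"))
  state <- staircase_init(config)
  state <- withr::with_seed(seed, {
    s <- state
    while (!s$terminated) {
      p <- observer_prob(observer, s$level)
      s <- staircase_step(s, stats::runif(1) < p)
    }
    s
  })
  traj <- dplyr::bind_rows(lapply(state$trajectory, tibble::as_tibble))
  converged <- length(state$reversal_levels) >= config$stop_reversals
  structure(
    list(trajectory = traj,
         reversal_levels = state$reversal_levels,
         threshold_estimate = if (length(state$reversal_levels) > 0)
           mean(state$reversal_levels) else NA_real_,
         converged = converged,
         n_trials = state$trial,
         seed = seed),
    class = "staircase_result"
  )
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf(
    "Staircase run: %d trials, %d reversals, threshold estimate = %.3f (%s)\n",
    x$n_trials, length(x$reversal_levels), x$threshold_estimate,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Safety/task adjustment of a threshold estimate
#'
#' The estimated thresholds are inflated before the main task: stimulation
#' power is set to 110% of the phosphene threshold (blindfolded estimation
#' underestimates the light-exposed threshold) and the orientation tilt to
#' 120% of the discrimination threshold (the memory task is harder than the
#' discrimination staircase).
#'
#' @param estimate Threshold estimate (finite).
#' @param factor Positive multiplier; see [phosphene_power_factor] and
#'   [orientation_tilt_factor].
#' @return `estimate * factor`.
#' @examples
#' adjust_threshold(60, phosphene_power_factor)   # 66% stimulator output
#' adjust_threshold(5.0, orientation_tilt_factor) # 6 degrees
#' @export
adjust_threshold <- function(estimate, factor) {
  if (!is.finite(estimate)) stop("`estimate` must be finite", call. = FALSE)
  if (!is.numeric(factor) || factor <= 0) {
    stop("`factor` must be a positive number", call. = FALSE)
  }
  estimate * factor
}

#' @rdname adjust_threshold
#' @format NULL
#' @export
phosphene_power_factor <- 1.10

#' @rdname adjust_threshold
#' @format NULL
#' @export
orientation_tilt_factor <- 1.20
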