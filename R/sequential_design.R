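# Deterministic per-replicate substream seeds: a fixed LCG-style hash of the
# master seed and replicate index, kept inside the 32-bit signed range so the
# replicate set is stable when n_sim changes.
.substream_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + i * 8191) %% 2147483629)
}

#' Hypothesis specification for design analysis
#'
#' Pairs a true standardized effect (the mean of the paired differences in
#' units of their standard deviation) with the Cauchy prior scale the
#' registered test uses.
#'
#' @param label Text label.
#' @param g True standardized effect of the paired differences.
#' @param r Cauchy prior scale, > 0.
#' @return A list of class `hypothesis_spec`.
#' @export
hypothesis_spec <- function(label, g, r) {
  if (!is.numeric(r) || r <= 0) stop("`r` must be > 0", call. = FALSE)
  structure(list(label = label, g = g, r = r), class = "hypothesis_spec")
}

#' Sequential design specification
#'
#' The registered sampling plan: recruit `n_min` participants, test all
#' hypotheses, and recruit in increments of `step` until every Bayes factor is
#' strictly outside (`bf_lower`, `bf_upper`) or `n_max` is reached.
#'
#' @param hypotheses List of [hypothesis_spec()] objects.
#' @param n_min,step,n_max Sampling plan (defaults 20 / 4 / 40).
#' @param bf_upper,bf_lower Evidence thresholds (defaults 3 and 1/3).
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(hypotheses, n_min = 20, step = 4, n_max = 40,
                        bf_upper = 3, bf_lower = 1 / 3) {
  if (n_min > n_max) stop("`n_min` must be <= `n_max`", call. = FALSE)
  if (step < 1) stop("`step` must be >= 1", call. = FALSE)
  if (!(bf_lower < 1 && 1 < bf_upper)) {
    stop("need bf_lower < 1 < bf_upper", call. = FALSE)
  }
  if (inherits(hypotheses, "hypothesis_spec")) hypotheses <- list(hypotheses)
  stopifnot(all(vapply(hypotheses, inherits, TRUE, "hypothesis_spec")))
  structure(list(n_min = n_min, step = step, n_max = n_max,
                 bf_upper = bf_upper, bf_lower = bf_lower,
                 hypotheses = hypotheses),
            class = "design_spec")
}

.fixed_n_summary <- function(bf, n_sim, bf_upper, bf_lower, seed) {
  structure(
    list(
      n_sim = n_sim,
      prop_above_upper = mean(bf > bf_upper),
      prop_below_lower = mean(bf < bf_lower),
      prop_inconclusive = mean(bf >= bf_lower & bf <= bf_upper),
      median_bf10 = stats::median(bf),
      bf10_quantiles = stats::quantile(bf, c(0.05, 0.25, 0.75, 0.95)),
      seed = seed
    ),
    class = "fixed_n_result"
  )
}

#' Fixed-n Bayes factor design analysis
#'
#' Monte-Carlo evaluation of the registered paired t-test at a fixed sample
#' size: each replicate draws `n` paired differences from Normal(g, 1),
#' computes the t statistic and the JZS Bayes factor with prior scale `r`, and
#' the replicate distribution of BF10 is summarized against the evidence
#' thresholds. Replicates use deterministic substreams of `seed`, so results
#' are fully reproducible and extending `n_sim` never reshuffles earlier
#' replicates.
#'
#' @param g True standardized effect (0 for the null branch).
#' @param r Cauchy prior scale.
#' @param n Participants per replicate (>= 2).
#' @param n_sim Number of Monte-Carlo replicates.
#' @param seed Master seed.
#' @param bf_upper,bf_lower Evidence thresholds (defaults 3, 1/3); boundary
#'   comparisons are strict.
#' @param keep_replicates If TRUE, attach a tibble (replicate, t, bf10) as the
#'   `replicates` attribute.
#' @return A `fixed_n_result`: boundary proportions (summing to 1), the median
#'   BF10 and its 5/25/75/95% quantiles, and the seed.
#' @export
simulate_fixed_n <- function(g, r, n = 40, n_sim = 10000, seed = 1,
                             bf_upper = 3, bf_lower = 1 / 3,
                             keep_replicates = FALSE) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (n_sim < 1) stop("`n_sim` must be >= 1", call. = FALSE)
  tv <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    d <- withr::with_seed(.substream_seed(seed, i), stats::rnorm(n, g, 1))
    tv[i] <- mean(d) / (stats::sd(d) / sqrt(n))
  }
  bf <- vapply(tv, function(t) bf10_jzs(t, n, r)$bf10, numeric(1))
  out <- .fixed_n_summary(bf, n_sim, bf_upper, bf_lower, seed)
  if (keep_replicates) {
    attr(out, "replicates") <-
      tibble::tibble(replicate = seq_len(n_sim), n = n, t = tv, bf10 = bf)
  }
  out
}

#' @export
print.fixed_n_result <- function(x, ...) {
  cat(sprintf(
    "Design analysis (%d replicates): P(BF10 > upper) = %.3f, P(BF10 < lower) = %.3f, inconclusive = %.3f\n",
    x$n_sim, x$prop_above_upper, x$prop_below_lower, x$prop_inconclusive))
  cat(sprintf("  median BF10 = %.4g\n", x$median_bf10))
  invisible(x)
}

#' Mixture design analysis (outcome-neutral branch weighting)
#'
#' Each replicate draws its true effect from a two-point mixture: with
#' probability `weight` the alternative branch (`h1`), otherwise the null
#' branch (`h0`). With equal weights this reproduces the combined
#' "either-boundary" rate of a design analysis that averages the
#' alternative-true and null-true scenarios.
#'
#' @param h1,h0 [hypothesis_spec()] objects for the two branches; the prior
#'   scale of `h1` is used for the Bayes factor.
#' @param weight Probability of the `h1` branch.
#' @inheritParams simulate_fixed_n
#' @return A `fixed_n_result`; `prop_above_upper + prop_below_lower` is the
#'   combined boundary-reaching proportion.
#' @export
simulate_mixture <- function(h1, h0, weight = 0.5, n = 40, n_sim = 10000,
                             seed = 1, bf_upper = 3, bf_lower = 1 / 3) {
  stopifnot(inherits(h1, "hypothesis_spec"), inherits(h0, "hypothesis_spec"))
  if (weight < 0 || weight > 1) stop("`weight` must be in [0, 1]",
                                     call. = FALSE)
  bf <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    d <- withr::with_seed(.substream_seed(seed, i), {
      g <- if (stats::runif(1) < weight) h1$g else h0$g
      stats::rnorm(n, g, 1)
    })
    t <- mean(d) / (stats::sd(d) / sqrt(n))
    bf[i] <- bf10_jzs(t, n, h1$r)$bf10
  }
  .fixed_n_summary(bf, n_sim, bf_upper, bf_lower, seed)
}

#' Sequential sampling simulation with the registered stopping rule
#'
#' Simulates the sample-updating procedure: each hypothesis evolves on its own
#' stream of paired differences, extended (never redrawn) as recruitment
#' grows. At each look n in `{n_min, n_min + step, ...}` all hypotheses' Bayes
#' factors are computed on the accumulated data; the run stops when every BF
#' is strictly outside (`bf_lower`, `bf_upper`), or at `n_max`.
#'
#' @param spec A [design_spec()].
#' @param n_sim Number of simulated studies.
#' @param seed Master seed.
#' @return A list of class `sequential_result`: `stopping_n_distribution` (a
#'   named proportion table over the looks), `mean_stopping_n`, per-hypothesis
#'   terminal boundary proportions (`upper`/`lower`/`none` at stop), and the
#'   seed.
#' @export
simulate_sequential <- function(spec, n_sim = 1000, seed = 1) {
  stopifnot(inherits(spec, "design_spec"))
  looks <- seq(spec$n_min, spec$n_max, by = spec$step)
  if (looks[length(looks)] < spec$n_max) looks <- c(looks, spec$n_max)
  nh <- length(spec$hypotheses)
  stop_n <- numeric(n_sim)
  terminal <- matrix("", n_sim, nh)

  for (i in seq_len(n_sim)) {
    # one stream of n_max differences per hypothesis, drawn up front
    streams <- lapply(seq_len(nh), function(j) {
      withr::with_seed(.substream_seed(seed, (i - 1) * nh + j),
                       stats::rnorm(spec$n_max, spec$hypotheses[[j]]$g, 1))
    })
    for (n in looks) {
      bfs <- vapply(seq_len(nh), function(j) {
        d <- streams[[j]][seq_len(n)]
        bf10_jzs(mean(d) / (stats::sd(d) / sqrt(n)), n,
                 spec$hypotheses[[j]]$r)$bf10
      }, numeric(1))
      done <- all(bfs > spec$bf_upper | bfs < spec$bf_lower)
      if (done || n == spec$n_max) {
        stop_n[i] <- n
        terminal[i, ] <- ifelse(bfs > spec$bf_upper, "upper",
                                ifelse(bfs < spec$bf_lower, "lower", "none"))
        break
      }
    }
  }

  hist <- table(factor(stop_n, levels = looks)) / n_sim
  per_hyp <- lapply(seq_len(nh), function(j) {
    c(upper = mean(terminal[, j] == "upper"),
      lower = mean(terminal[, j] == "lower"),
      none = mean(terminal[, j] == "none"))
  })
  names(per_hyp) <- vapply(spec$hypotheses, `[[`, "", "label")
  structure(
    list(n_sim = n_sim,
         stopping_n_distribution = hist,
         mean_stopping_n = mean(stop_n),
         boundary_proportions = per_hyp,
         seed = seed),
    class = "sequential_result"
  )
}

#' @export
print.sequential_result <- function(x, ...) {
  cat(sprintf("Sequential design analysis (%d simulated studies)\n", x$n_sim))
  cat(sprintf("  mean stopping n = %.2f\n", x$mean_stopping_n))
  print(round(x$stopping_n_distribution, 3))
  invisible(x)
}

#' Bayes factor trajectory over sequential looks
#'
#' Evaluates the Bayes factor on growing prefixes of a single stream of paired
#' differences, the quantity plotted in a sequential-analysis curve. A look
#' whose prefix is degenerate (zero standard deviation) is recorded with an
#' `NA` Bayes factor and a note; the trajectory continues.
#'
#' @param differences Accumulated paired differences in arrival order.
#' @param r Cauchy prior scale.
#' @param looks Increasing vector of look sizes, each >= 2 and <= the stream
#'   length.
#' @return A tibble with columns `n`, `bf10`, `log_bf10`, `t`, `note`.
#' @export
evidence_trajectory <- function(differences, r, looks) {
  if (any(looks < 2)) stop("every look must be >= 2", call. = FALSE)
  if (is.unsorted(looks, strictly = TRUE)) {
    stop("`looks` must be strictly increasing", call. = FALSE)
  }
  if (max(looks) > length(differences)) {
    stop("largest look exceeds the stream length", call. = FALSE)
  }
  rows <- lapply(looks, function(n) {
    res <- tryCatch({
      ts <- t_statistic(differences[seq_len(n)])
      bf <- bf10_jzs(ts$t, ts$n, r)
      tibble::tibble(n = n, bf10 = bf$bf10, log_bf10 = bf$log_bf10,
                     t = bf$t, note = NA_character_)
    }, error = function(e) {
      tibble::tibble(n = n, bf10 = NA_real_, log_bf10 = NA_real_,
                     t = NA_real_, note = conditionMessage(e))
    })
    res
  })
  dplyr::bind_rows(rows)
}
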