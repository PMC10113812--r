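#' Paired t statistic from a vector of differences
#'
#' Reduces a vector of paired condition differences (one per participant) to
#' the one-sample t statistic that feeds the Bayes factor engine.
#'
#' @param differences Numeric vector of paired differences, length >= 2.
#' @return A list with elements `t` (the statistic, using the unbiased n-1
#'   sample standard deviation) and `n` (the sample size).
#' @examples
#' t_statistic(c(0.2, -0.1, 0.3, 0.0))
#' @export
t_statistic <- function(differences) {
  if (!is.numeric(differences) || length(differences) < 2) {
    stop("`differences` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (anyNA(differences)) {
    stop("`differences` must not contain missing values", call. = FALSE)
  }
  s <- stats::sd(differences)
  if (s == 0) {
    stop("degenerate data: the differences have zero standard deviation, ",
         "the t statistic and Bayes factor are undefined", call. = FALSE)
  }
  n <- length(differences)
  list(t = mean(differences) / (s / sqrt(n)), n = n)
}

# Log of the marginal-likelihood integrand for the JZS Bayes factor in the
# mixture-of-g representation: a Cauchy(0, r) prior on the standardized effect
# delta is equivalent to delta | g ~ N(0, g) with g ~ InvGamma(1/2, r^2/2).
# The noncentral-t marginal then has the closed elementary form below
# (no noncentral special functions needed). Parameterized as g = r^2 * h so the
# integrand peaks at h = O(1) for every prior scale.
.jzs_log_integrand_h <- function(h, t, n, r) {
  v <- n - 1
  g <- r^2 * h
  -0.5 * log1p(n * g) -
    (v + 1) / 2 * log1p(t^2 / ((1 + n * g) * v)) +
    0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - 1 / (2 * h) + 2 * log(r)
}

#' Default (Jeffreys-Zellner-Siow) Bayes factor for a paired/one-sample design
#'
#' Computes the two-sided Bayes factor BF10 comparing H1, a zero-centred Cauchy
#' prior with scale `r` on the standardized effect delta, against the point
#' null delta = 0, from the t statistic of n paired differences.
#'
#' The marginal likelihood under H1 is the noncentral-t density averaged over
#' the Cauchy prior. It is evaluated through the equivalent inverse-gamma
#' mixture-of-g representation (delta | g ~ N(0, g), g ~ InvGamma(1/2, r^2/2)),
#' whose integrand involves only elementary functions, with adaptive quadrature
#' on a scale-normalized bounded substitution and log-space max-shifting so the
#' result is stable for prior scales from 1e-6 up and |t| into the hundreds.
#' The symmetric prior covers both signs of the effect, so the test is
#' two-sided: BF10(t) = BF10(-t).
#'
#' @param t Paired t statistic (finite).
#' @param n Number of pairs, >= 2.
#' @param r Cauchy prior scale ("width"), > 0. The study's registered widths
#'   were 0.58, 0.8 and 0.5 for the 0, 200 and 1000 ms comparisons.
#' @return An object of class `bf_result`: a list with `bf10`, `log_bf10`,
#'   `t`, `n`, `r` and `quadrature_error` (the integrator's absolute-error
#'   estimate on the marginal likelihood).
#' @examples
#' bf10_jzs(t = 2.5, n = 36, r = 0.8)
#' @export
bf10_jzs <- function(t, n, r) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t)) {
    stop("`t` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0) {
    stop("`r` must be a single positive number", call. = FALSE)
  }
  v <- n - 1
  # locate the integrand maximum on a wide log grid, then integrate the
  # max-shifted integrand over h mapped to (0, 1)
  h_grid <- exp(seq(log(1e-6), log(1e8), length.out = 400))
  log_m <- max(.jzs_log_integrand_h(h_grid, t, n, r))
  f <- function(u) {
    h <- u / (1 - u)
    exp(.jzs_log_integrand_h(h, t, n, r) - log_m) / (1 - u)^2
  }
  quad <- tryCatch(
    stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-300,
                     subdivisions = 500L),
    error = function(e) {
      stop("numerical accuracy error in Bayes factor quadrature (t = ", t,
           ", n = ", n, ", r = ", r, "): ", conditionMessage(e), call. = FALSE)
    }
  )
  log_marg1 <- log_m + log(quad$value)
  log_marg0 <- -(v + 1) / 2 * log1p(t^2 / v)   # log central-t density, up to
  # the normalizing constant shared by numerator and denominator
  log_bf10 <- log_marg1 - log_marg0
  structure(
    list(
      bf10 = exp(log_bf10),
      log_bf10 = log_bf10,
      t = t,
      n = as.integer(n),
      r = r,
      quadrature_error = quad$abs.error * exp(log_m)
    ),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("JZS Bayes factor: BF10 = %.4g (log BF10 = %.4f)\n",
              x$bf10, x$log_bf10))
  cat(sprintf("  t = %.4f, n = %d, Cauchy prior scale r = %g\n",
              x$t, x$n, x$r))
  invisible(x)
}

#' Paired-samples Bayes factor from two condition vectors
#'
#' Convenience wrapper: computes the elementwise differences `x - y`, reduces
#' them with [t_statistic()] and evaluates [bf10_jzs()].
#'
#' @param x,y Numeric vectors of equal length >= 2 (one value per
#'   participant, e.g. ipsilateral and contralateral d-prime).
#' @param r Cauchy prior scale.
#' @return A `bf_result` object.
#' @export
bf10_paired <- function(x, y, r) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  ts <- t_statistic(x - y)
  bf10_jzs(ts$t, ts$n, r)
}

#' Prior-width robustness curve for a Bayes factor
#'
#' Recomputes the Bayes factor at the narrow (r = 0.3), wide (r = 1) and
#' ultrawide (r = 1.5) Cauchy scales alongside the registered scale, the
#' standard check that a conclusion does not hinge on the preregistered prior
#' width.
#'
#' @param t Paired t statistic.
#' @param n Number of pairs.
#' @param registered_r The preregistered Cauchy scale.
#' @return A tibble with columns `r` and `bf10`, sorted by `r`, containing
#'   r = 0.3, the registered scale, 1.0 and 1.5; the registered scale is kept
#'   in the `registered_r` attribute.
#' @export
bf_robustness <- function(t, n, registered_r) {
  scales <- sort(unique(c(0.3, registered_r, 1.0, 1.5)))
  out <- tibble::tibble(
    r = scales,
    bf10 = vapply(scales, function(s) bf10_jzs(t, n, s)$bf10, numeric(1))
  )
  attr(out, "registered_r") <- registered_r
  out
}
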