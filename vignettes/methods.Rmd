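---
title: "Methods: the Bayes factor engine, design analysis and d-prime pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Bayes factor engine, design analysis and d-prime pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vstmtms)
```

This vignette is the package's own account of its science: the models and
procedures it implements, the assumptions behind them, every numerical and
design choice that was genuinely open, and what the tests do and do not
establish.

## The default Bayes factor for paired designs

The registered tests are Bayesian paired t-tests. Let d be the vector of
paired condition differences (e.g. ipsilateral minus contralateral d′, one
per participant), n their number, and t the one-sample t statistic computed
with the unbiased (n − 1) standard deviation. The hypotheses concern the
standardized effect δ (mean of the differences in units of their standard
deviation):

* H₀: δ = 0;
* H₁: δ ~ Cauchy(0, r), a zero-centred Cauchy prior whose scale ("width") r
  is set per test — 0.58, 0.8 and 0.5 for the three timing conditions,
  informed by meta-analytic effect sizes. The notation B_C(0, .58) is read
  as Cauchy(location 0, scale 0.58).

The Bayes factor is the marginal-likelihood ratio

BF₁₀ = ∫ f(t; ν, δ√n) Cauchy(δ; 0, r) dδ / f(t; ν, 0),

with f the noncentral-t density and ν = n − 1. The prior is symmetric, so
the test is two-sided — BF₁₀(t) = BF₁₀(−t) — and no one-sided variant is
exposed: the registered hypotheses ask whether the difference "differs from
zero", not in which direction.

### Numerical evaluation

A zero-centred Cauchy is an inverse-gamma scale mixture of normals:
δ | g ~ N(0, g) with g ~ InvGamma(1/2, r²/2). Marginalizing δ analytically
leaves a one-dimensional integral over g whose integrand involves only
elementary functions (the classic closed form used for default t-test Bayes
factors). `bf10_jzs()` evaluates that integral rather than the noncentral-t
form because the noncentral-t density is exactly the special function that
numerical libraries evaluate least reliably at large noncentrality; the
elementary integrand has no such weak spot and is cheap enough to vectorize.
Concretely:

* the integrand is computed entirely in log space, using `log1p` forms, and
  parameterized as g = r²·h so its peak sits at h = O(1) for every prior
  scale (the behaviour at r = 10⁻⁶ and r = 1.5 is numerically identical);
* h is mapped to the unit interval by h = u/(1 − u) and integrated
  adaptively (`stats::integrate`, relative tolerance 10⁻¹⁰) after
  subtracting the maximum of the log integrand located on a 400-point log
  grid spanning h ∈ [10⁻⁶, 10⁸];
* the result is returned in both log and linear form; the linear form can
  overflow to infinity only beyond log BF₁₀ > 709, the log form never does;
* the integrator's absolute-error estimate on the marginal likelihood is
  reported as `quadrature_error`.

The test suite cross-checks this route against a deliberately different
one: brute-force fixed-grid trapezoid quadrature of the noncentral-t ×
Cauchy integrand over δ ∈ ±50r (2 × 10⁵–2 × 10⁶ points). The two routes
agree to ~10⁻¹¹ relative error across random (t, n, r); the acceptance
tolerance is 10⁻⁵. Limiting behaviour is asserted exactly where theory
fixes it: BF₁₀ < 1 at t = 0, BF₁₀ → 1 as r → 0 (the prior collapses onto
the null), symmetry in t, and strict monotonicity in |t|.

## Bayes factor design analysis

`simulate_fixed_n()` draws each replicate's paired differences from
Normal(g, 1): g is the true standardized effect, and the unit standard
deviation is without loss of generality because t and BF₁₀ are scale
invariant. This is the plainest reading of "a true effect of g". Replicates
use deterministic substreams of the master seed (an LCG-style hash of seed
and replicate index), so a run is bit-reproducible and extending `n_sim`
never reshuffles earlier replicates.

Under the null (g = 0) at n = 40 this generator reproduces the registered
calibration: BF₁₀ < 1/3 in ≈ 70% / 80% / 63% of replicates with median
BF₁₀ ≈ 0.25 / 0.19 / 0.28 at r = 0.58 / 0.8 / 0.5 — the quantities
`scripts/acceptance.R` recomputes at 10 000 replicates (the test suite uses
2 000 and ±3 Monte-Carlo standard errors).

The alternative branch is a different matter. Under Normal(g = 0.58, 1) at
n = 40, the upper boundary is reached in roughly 87% of replicates and the
median BF₁₀ is on the order of 50 (see `analysis/01_design_analysis.R`) —
high, but nowhere near certainty, and many orders of magnitude below a
median in the millions. Alternative-branch certainties of that size are not
derivable from this generative reading; they would require a generator with
essentially no sampling variability in the realized effect. The package
therefore treats the alternative branch as a property surface rather than a
number-matching target: the median BF₁₀ under g = 0.58 must exceed 3 and
grow with n, and P(BF₁₀ > 3) must rise monotonically in g at fixed (n, r).

`simulate_sequential()` implements the registered plan: per-hypothesis
streams of differences drawn up front at n_max and extended, never redrawn,
as looks proceed (matching how a real cohort accrues); looks at
n = 20, 24, …, 40; stop at the first look where every BF₁₀ is strictly
outside (1/3, 3), else at n_max. Boundary comparisons are strict throughout
(">" and "<"), and the thresholds live in exactly one place
(`analysis_config()` for the pipeline, `design_spec()` for simulations).
Each hypothesis gets its own independent stream: in reality the three tests
share participants, but the shared-participant correlation structure of
*effects* is unknown, and stopping decisions depend on the joint crossing
pattern far less than on the marginal evidence trajectories; the synthetic
cohort + `sequential_monitor()` route covers the shared-participant case
end to end.

## The d′ pipeline

Detection sensitivity is d′ = z(H) − z(FA): H the hit rate ("same"
responses on same-probe trials), FA the false-alarm rate ("same" responses
on changed-probe trials), z the standard normal quantile. The pipeline
applies, in order:

1. **Participant QC** — exclusion when overall accuracy over recorded
   experimental trials is strictly below 60% or data loss is strictly above
   20% of planned trials. Accuracy counts a no-response trial as incorrect
   (it drew the same "Wrong!" feedback as an error and encodes no
   decision). QC precedes trial filtering because participant exclusion is
   listed before trial exclusion in the registered filtering rules.
2. **Reaction-time filter** — per participant, mean and standard deviation
   over all responded trials computed once, removal of trials strictly
   beyond 3 s.d. from the mean, single pass, no iteration (the study
   reports a single exclusion percentage per participant). The filter is by
   construction one-shot: re-running it on its own output recomputes bounds
   and may remove more, so the contract tested is the single pass, not
   idempotence. A global (not per-condition) mean is used, matching "each
   participant's mean reaction time".
3. **Rates and d′** — per design cell (6 cells in the 2 × 3 experiment, 8
   in the 2 × 2 × 2). No-response trials are dropped from both
   denominators by default (`"count_as_different"` is available for
   sensitivity analysis, since the original treatment is unknown). Rates of
   exactly 0 or 1 are clamped to 1/(2n) and 1 − 1/(2n) under the default
   `"half_count"` correction — the standard extreme-proportion remedy,
   chosen because it preserves the d′ formula itself — or raise an error
   under `"none"`. Missing cells are reported, never imputed; cells left
   without signal or noise trials raise errors carrying the participant and
   cell identity.

### Estimator bias, and how recovery is measured

The per-participant plug-in d̂′ is biased upward at finite trial counts:
with 36 signal and 36 noise trials, the convexity of the z transform
inflates the mean estimate by ≈ +0.02 at d′ = 0.7 up to ≈ +0.06 at
d′ = 1.65 (measured by simulation). That is estimator bias, not generator
error, so the generator round-trip test pools hit and false-alarm counts
across 500 homogeneous participants per cell — "empirical per-cell d′
across many participants" — where the transform bias is negligible and the
generator must land within 0.02 of truth (and does, within binomial
standard errors per cell).

Relatedly, the accuracy gate truncates the participant distribution: the
excluded participants are the weakest, so the included cohort's true mean
d′ sits above the population cell mean (by ≈ +0.15 at the default
between-participant s.d.). The end-to-end check therefore compares pipeline
condition means against the realized ground truth of the included cohort —
the comparison the study itself makes, since excluded participants were
replaced — using the generator's ground-truth sidecar.

## Staircase procedures

Two transformed up-down rules are implemented verbatim:

* **2-down-1-up consecutive** (phosphene power threshold): power drops one
  step after two consecutive phosphene reports at the same power, rises
  after every failure;
* **3-down-1-up consecutive** (orientation threshold): tilt drops after
  three consecutive correct discriminations, rises on any error.

The "consecutive" counter resets after any level change and after any
negative response — the strictest reading. A reversal is a trial whose
prescribed level change has opposite sign to the previous nonzero change;
levels are clamped to bounds but the prescribed direction still drives
reversal logic at a bound. The threshold estimate is the arithmetic mean of
the reversal levels. Asymptotically these rules converge to the levels
where the positive-response probability is 0.5^(1/2) ≈ 70.7% and
0.5^(1/3) ≈ 79.4%; the procedures' own "50%" and "75%" labels are treated
as the conventional approximations they are, and the calibration tests
target the theoretical quantiles (mean estimate within one step over 500
seeded runs against a steep logistic observer).

Unstated parameters were fixed once: step sizes default to 5 percentage
points of stimulator output (consistent with the 5% increments used during
localization) and 1° of tilt; termination at 8 reversals or 200 trials.
The post-estimation adjustments are exact arithmetic: ×1.10 for phosphene
power, ×1.20 for orientation tilt.

## The synthetic generator

`generate_experiment()` emulates the statistical structure the analysis
assumes, not the psychophysics that produced it. Per cell: 72 trials, half
same-probe, a quarter each clockwise/counter-clockwise; an equal-variance
Gaussian observer with hit probability Φ(d′/2 − c) and false-alarm
probability Φ(−d′/2 − c) (the task's two change directions are collapsed to
signal/noise, exactly as the d′ formula assumes); participant-level d′ is
the cell mean plus a multivariate-normal deviation shared across cells with
standard deviation `between_sd` (default 0.65, the scale of the published
condition s.d.s) and pairwise correlation `cross_corr` (default 0.7 — a
convention, since no within-participant cross-condition correlation is
reported; it is exposed in the specification). Default cell means are the
published condition means of the two experiments. With c = 0 and d′ ≈ 1.2
the implied accuracy is ≈ 72%, matching the reported cohorts.

Reaction times are lognormal(log 700, 0.3) ms; with probability 0.035 a
trial's time is inflated ×10 and truncated at the 3000 ms response window,
so the 3-s.d. filter removes ≈ 3.5% of trials — the reported exclusion
rates (3.5% / 3.7%). Nonresponses occur with probability 0.01. A
participant deviation that would push a response probability outside (0, 1)
is clamped to 10⁻⁴ from the boundary with a warning, rather than resampled,
keeping the generator total and its warnings visible. Everything is
deterministic given the seed (per-participant substreams), and a JSON
ground-truth sidecar records every realized parameter, so any generated
quantity can be recomputed.

What the generator does **not** emulate: learning or fatigue across blocks,
criterion drift, reaction-time/accuracy coupling, serial dependence between
trials, and any neurophysiology of stimulation. Passing tests therefore
demonstrate that the pipeline recovers the parameters of data satisfying
its own assumptions — not that real cohorts satisfy them.

## Registered hypotheses and the pipeline

`registered_hypotheses()` carries the preregistered bindings: H1–H3 are the
site comparisons (ipsilateral vs contralateral d′) of the first experiment
at 0/200/1000 ms with r = 0.58/0.8/0.5; H4 and H6 replicate the 200 and
1000 ms site comparisons in the second experiment on real-TMS trials only
(sham excluded); H5 and H7 compare real against sham at 200 and 1000 ms
across hemispheres. "Across hemispheres" is implemented as the unweighted
mean of the participant's ipsilateral and contralateral cell d′ within each
stimulation condition, then real − sham differencing; whether the original
analysis averaged cell d′ or pooled trials before computing d′ is unknown,
so the alternative (`hemisphere_pooling = "pool_trials"`) is a
configuration switch. Decisions are three-way at the strict thresholds:
supports-H₁ above 3, supports-H₀ below 1/3, else inconclusive. Degenerate
hypotheses (zero-variance differences, missing cells) are reported with
reasons, never silently dropped, and reports serialize deterministically
with a configuration fingerprint.

## Problem sizes and runtime choices

The package's own test and script sizes: 2 000 replicates for the
design-analysis reproduction in the test suite (±3 Monte-Carlo standard
errors; the acceptance script uses the full 10 000), 100–500 seeded runs
for staircase calibration, 500 participants for generator round-trips, 10
synthetic cohorts for the sequential-monitor check, and oracle sweeps of
100 random triples. These sizes put every Monte-Carlo tolerance at least
three standard errors wide while keeping a full run in minutes.

## Known limitations

* The printed per-hypothesis Bayes factors of the study's results tables
  require the deposited trial data; the pipeline reproduces them only in
  shape (synthetic cohorts at the published condition means), not in value.
* The alternative-branch design-analysis certainties are not reproducible
  under the Normal(g, 1) generator, as discussed above.
* No Bayes-factor repeated-measures ANOVA / inclusion BFs, no posterior
  estimation or credible intervals, and no one-sided Bayes factors.
* The equal-variance observer is an assumption of the d′ formula itself;
  unequal-variance signal detection is out of scope.
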