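---
title: "Evaluating vaccine-safety surveillance designs on synthetic data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating vaccine-safety surveillance designs on synthetic data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Post-marketing vaccine-safety surveillance asks whether an adverse outcome
occurs more often shortly after vaccination than expected. Routinely
collected claims and EHR data make it possible to monitor many outcomes
monthly, but every epidemiological design that can be run on such data —
historical comparator, concurrent cohort, case-control, self-controlled case
series (SCCS) and self-controlled risk interval (SCRI) — carries its own
systematic error, and repeated monthly testing inflates the false-positive
rate unless the sequential multiplicity is controlled.

`vaxeval` rebuilds this method-evaluation problem on synthetic data with
known truth. The package simulates a longitudinal observational database
with configurable confounding, runs 25 design variants under monthly
sequential looks, applies maximized sequential probability ratio testing
(MaxSPRT) and empirical calibration, and measures type 1 error, type 2 error
and time to 50% sensitivity. Because the generator controls the true effect
of vaccination on every outcome, every downstream stage is testable: the
negative controls really are null, and the injected positives really carry
the effect size they claim.

# The synthetic database

`sim_config()` + `simulate_tables()` produce five OMOP-style tables
(person, observation_period, visit_occurrence, vaccination, outcome). The
default scenario is a nine-month pandemic-style vaccination campaign
(September 2009 through May 2010) preceded by a nine-month historic period,
with a 28-day time-at-risk (TaR, days 1–28 after each dose).

Confounding is generated by two latent per-person scalars:

* **frailty** — a lognormal multiplier (mean 1, log-scale s.d.
  `frailty_sd = 0.7`) on all outcome rates;
* **health-seeking** — a standard-normal score.

Both raise the outpatient-visit rate and the monthly vaccination hazard
log-linearly. The defaults (`frailty_uptake_strength = 0.4`,
`frailty_visit_strength = 1.2`, `health_seeking_strength = 0.5`) encode two
mechanisms that real claims data exhibit:

1. *Vaccinated people differ from the unvaccinated.* Because frailty raises
   the vaccination hazard, vaccinees are frailer than average, which biases
   any between-person comparison against an average-population expectation
   (historical comparator, case-control, random-day cohort comparator)
   upward.
2. *People in care on a given day differ from the population.* Because
   frailty raises the visit rate more strongly than the vaccination hazard,
   a comparator anchored to an outpatient visit is *frailer than the
   vaccinees*, flipping the cohort bias negative. A comparator anchored to
   a random day samples (mostly never-vaccinated) healthier people and is
   biased positive. This anchor-dependent sign flip is a central behaviour
   the evaluation must reproduce, and it does (see
   `results/tables/estimates_summary.csv` and the acceptance suite).

Self-controlled designs compare each person with themselves, so the frailty
multiplier cancels from the conditional likelihood; SCCS and SCRI stay
centred on the null under the same confounding.

Other generator choices, with rationale:

* **Baseline rates** are log-spaced over 0.008–0.05 events per person-year
  across the 93 negative controls. Real negative-control outcomes are far
  rarer, but real databases hold tens of millions of patients; at a
  desk-scale 20,000 persons these rates give each outcome enough events for
  most variants to produce an estimate while keeping first-event depletion
  (see *Limitations*) mild.
* **Campaign coverage** is ~19% of the population, shaped like a campaign
  (peak in months 2–4). Low coverage keeps the comparator pools
  representative, as in real databases where a single vaccine reaches a
  small fraction of the covered population.
* **Seasonality** is a sinusoid (`amplitude = 0.3`, peak mid-January)
  multiplying all outcome rates; age effects are not simulated. The
  season-adjusted SCCS's splines can absorb the sinusoid; a 5-knot cubic
  B-spline basis over calendar time (and one over age) is the concrete
  reading we chose for "spline adjustment for age and season", with knots
  equally spaced over the in-sample range.
* **First occurrences only.** Outcomes are defined as the first occurrence
  per person, matching first-diagnosis outcome definitions; the generator
  simulates the underlying recurrent process and truncates.
* **Time arithmetic.** Days are the unit; person-years use 365.25 days; the
  TaR window is closed (`[vaccination + 1, vaccination + 28]`); day 0 (the
  vaccination day) belongs to neither risk nor control time.
* **Observation.** 90% of persons are observed from the historic-period
  start (which automatically satisfies the 365-day prior-observation
  eligibility rule all non-historical designs apply); the rest enter at a
  random later date; 5% leave early. TaR person-time is truncated at
  observation end.

What the generator deliberately does **not** emulate: vocabulary-coded
concepts, coding-practice drift, enrollment gaps, event-dependent
observation end, dose-specific effects, or confounding that acts through
measured covariates only. Passing tests on this generator therefore show
that each estimator does what its theory promises under the simulated
mechanisms — not that any variant is unbiased on real claims data, where
the confounding structure is unknown.

# The design variants

All 25 variants share the estimates schema (one row per design × variant ×
outcome × look × true effect size) produced by `run_grid()`.

**Historical comparator (8 variants).** `historic_rate()` estimates the
background rate from the historic period, either from all person-time or
from one random outpatient visit per person followed by a TaR-length
window ("post-visit" anchor), optionally stratified by 5-year age band and
sex. `expected_count()` multiplies rates by the vaccinees' TaR person-time;
`estimate_irr()` forms the observed/expected ratio with an exact Poisson
(Garwood) interval, upper-tail Poisson p, and the Poisson MaxSPRT LLR. The
"filtered" variants drop an outcome at a look when its overall rate moved
more than 50% between the historic and surveillance-so-far periods.
Vaccinees who aged past the oldest historically observed age band borrow
the nearest band's rate (same sex) rather than aborting the variant.

**Concurrent cohort (10 variants).** Comparators are anchored on an
outpatient-visit day (persons enter proportionally to their visit
frequency) or a random observed day, excluding anyone vaccinated on or
before the candidate index. Unadjusted variants sample 1:1; adjusted
variants sample 2:1 (the pandemic-scenario ratio) and fit an L1-regularised
propensity model (`glmnet`, penalty by 5-fold cross-validation) on a
generic covariate set: per-outcome history indicators over a 365-day
lookback, age (continuous and banded), sex, prior-year visit count and
index month — frailty and health-seeking themselves are withheld, as
unmeasured confounders. Adjustment is 1:1 greedy nearest-neighbour matching
on logit PS with a 0.2-s.d. caliper, PS-quintile stratification, or ATT
weighting truncated at the comparators' 99th weight percentile. Outcomes
are analysed as time-to-first-event in the TaR with a Cox model (Breslow
ties), stratified by matched pair/stratum, robust SEs when weighted;
comparators are censored at any later vaccination. The per-month variants
match within each calendar month at its first look and freeze the matches
thereafter.

**Case-control (2 variants).** Cases are first occurrences in the study
period with 365 days of prior observation; up to 4 controls per case are
either matched on 5-year age band and sex (index = case's outcome date) or
drawn at random with index dates resampled from the case outcome-date
distribution. Exposure is a vaccination in the mirror of the TaR
(`[index − 28, index − 1]`). Estimation is conditional logistic over
matched sets, or unconditional logistic with age-band and sex terms.

**SCCS/SCRI (5 variants).** `build_intervals()` paints each vaccinated
case's in-study days as risk (days 1–28 after any dose), excluded, or
control, with precedence risk > excluded > control: the pre-30 variants
exclude days −30..0 around each dose; the all-post variant excludes
everything before day 1 of the first dose; the SCRI variants use exactly
days −43..−15 (pre) or +43..+71 (post) as control. The SCCS conditional
Poisson likelihood is fitted as a Poisson regression with person fixed
effects and a log-length offset (identical profile for the exposure
coefficient); SCRI uses the conditional binomial with the exact
Clopper–Pearson interval mapped to the rate-ratio scale.

Every variant flags cells it cannot estimate (`estimable = FALSE` with a
reason: no cases, zero events in an arm, monotone conditional likelihood,
instability-filtered) rather than dropping them.

# Sequential testing

MaxSPRT compares a log-likelihood ratio accumulated over monthly looks
against a flat critical value whose any-look null crossing probability is
the design alpha (0.05). `poisson_llr()` serves the historical comparator
(observed vs expected counts); `binomial_llr()` serves the self-controlled
designs (risk-window events among total events, null proportion
`1/(1+z)` with `z` the control-to-risk time ratio); designs whose native
output is a Wald pair (cohort, case-control) use the normal-approximation
LLR `max(0, θ̂)²/(2·SE²)` so that the same machinery applies uniformly.

Critical values are computed by seeded Monte Carlo (`critical_value()`):
simulate null increments over the observed cumulative schedule, take each
replicate's maximum LLR, and use the ⌈(1−α)·R⌉-th order statistic as the
boundary (default R = 10⁵; the grid uses 2·10⁴ per outcome). The single-look
Poisson case is cross-checked against the exact tail sum in the test suite,
and a separate experiment (`maxsprt_alpha_experiment()`) verifies with
fresh seeds that the boundary's any-look crossing probability does not
exceed alpha beyond Monte-Carlo error. Because each outcome's schedule is
its own observed event accrual, one critical value is computed per
(variant, outcome) from the full observed schedule. Signals persist once
declared.

# Empirical calibration

Negative controls have true log effect 0, so their estimates should scatter
around 0 with spread given by their SEs. `fit_null()` models the excess as
Gaussian systematic error: `θ̂ᵢ ~ N(μ, τ² + seᵢ²)`, maximised by L-BFGS-B
with an analytic gradient from multiple starts, with the τ = 0 boundary
checked by a profile. `calibrate_p()` recomputes the one-sided p against
the shifted, widened null; `calibrate_llr()` is the matching
normal-approximation LLR, chosen for its exact reduction to the
uncalibrated statistic when (μ, τ) = (0, 0).

One numerical choice deserves emphasis: the naive plug-in calibration
`1 − Φ((θ̂ − μ̂)/√(τ̂² + se²))` rejects slightly more than 5% of
model-consistent negatives (≈5.24% measured over 400 replicates at 93
controls) because it ignores the sampling error of (μ̂, τ̂). When given a
full `fit_null()` object, `calibrate_p()` therefore adds the fitted mean's
variance `1/Σwᵢ` to the predictive variance and uses a Student-t reference
with Satterthwaite degrees of freedom from the curvature of the τ²
estimate; the measured rate is then 4.96% ± 0.09%. A bare `(μ, τ)` list
still evaluates the plain formula.

Calibration in the pipeline is leave-one-out per (design, variant, look):
each negative control is calibrated against the fit excluding itself, and
each imputed positive against the fit excluding its parent negative.
Positive controls are imputed by multiplying a negative control's estimated
effect size by 1.5, 2 and 4 (log-shift; SE and counts carried over), which
encodes the assumption that systematic error does not change with the true
effect size.

# Performance metrics

`type1_error()` is the fraction of estimable negatives rejected (one-sided
p < 0.05, or LLR > CV in sequential mode); `type2_error()` the fraction of
positives of a given size not rejected; `time_to_sensitivity()` the
earliest look by which at least 50% of a size's positives have signalled
(calibrated LLR above the critical value at that or an earlier look —
signals persist; the 80% variant is a parameter change).
`summarize_performance()` produces one row per variant and the four figure
archetypes (estimate-vs-SE funnels, fitted error distributions, type 1/2
bars pre/post calibration, months-to-sensitivity tiles) are produced by the
`plot_*` functions.

# Problem sizes and workflow

The `analysis/` scripts run the workflow end to end at the sizes we chose
for a desk-scale study: 20,000 persons, 93 negative controls, the full
25-variant grid at three looks (months 3, 6, 9), positive controls imputed
at ×1.5/×2/×4, and 2·10⁴ Monte-Carlo replicates per critical value. The
validation suite uses the same population size for the confounding-bias
checks, 100 simulated datasets for the SCCS parameter-recovery check, and
10⁵ replicates for the alpha-control experiment. The acceptance script
(`scripts/acceptance.R`) recomputes the worked-example LLR, the calibrated
type 1 error under injected systematic error, and the MaxSPRT any-look
crossing probability from scratch under a caller-supplied seed.

# Known limitations

* **First-event depletion.** With first-occurrence outcomes, frail persons
  are preferentially removed from the at-risk population over time. At the
  chosen baseline rates this drift is small, but estimates for different
  outcomes share one simulated population, so their errors are correlated
  and across-outcome mean log estimates wobble by roughly ±0.1 between
  seeds; thresholds in the validation suite account for this.
* **SCRI and seasonality.** With campaign-shaped uptake and seasonal
  rates, a pre-vaccination control interval sits systematically earlier in
  the season than the risk window, so SCRI is genuinely season-confounded
  in the default scenario. The confounding-robustness checks therefore run
  with seasonality off to isolate between-person confounding; with
  seasonality on, the bias is a real property of the design, not an
  artifact.
* **Critical values are retrospective.** Each (variant, outcome) boundary
  is computed from the full observed look schedule rather than updated
  look-by-look with predicted future information, matching a retrospective
  method evaluation rather than a live surveillance system.
* The cohort outcome model is proportional hazards with Breslow ties, and
  comparators are censored at later vaccination; both are conventional
  choices where several defensible alternatives exist.
* The per-set audit files, multi-database meta-analysis, CI calibration
  and vocabulary-driven outcome definitions are out of scope.
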