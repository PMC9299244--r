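# vaxeval

Empirical evaluation of vaccine-safety surveillance designs on synthetic
longitudinal health data with known truth.

## The problem

Safety surveillance on routinely collected healthcare data monitors many
vaccine–outcome pairs month by month and must declare true risks early
without flooding reviewers with false positives. Every design that can be
run on such data carries its own systematic error: a **historical
comparator** compares observed post-vaccination counts against an expected
count `u` from a pre-launch incidence rate; a **concurrent cohort** compares
vaccinees against a sampled non-vaccinated cohort (optionally adjusted with
large-scale propensity scores); a **case-control** design looks back from
cases for recent vaccination; **SCCS/SCRI** compare each person's risk
window (days 1–28 after vaccination) against their own unexposed time.
Repeated monthly testing is controlled with MaxSPRT: the log-likelihood
ratio

```
LLR = c·ln(c/u) − (c − u)        (Poisson form, c observed, u expected)
```

is compared at each look against a critical value whose *any-look* null
crossing probability is alpha = 0.05. Residual bias is measured with
negative-control outcomes (true rate ratio 1) and removed by **empirical
calibration**: a Gaussian systematic-error model `θ̂ᵢ ~ N(μ, τ² + seᵢ²)` is
fitted to the negative-control log estimates and p-values/LLRs are
recomputed against the shifted, widened null. Type 2 error is measured on
positive controls imputed from the negatives by multiplying the estimated
effect size by 1.5, 2 and 4.

Real evaluations of this kind run on licensed claims/EHR databases that
cannot be shared. `vaxeval` instead *simulates* the database — persons,
observation periods, outpatient visits, confounded vaccination uptake,
seasonal outcome rates, negative and injected positive control outcomes —
so the whole pipeline is reproducible and every stage can be tested against
known truth. The package implements all 25 design variants (2 case-control,
10 cohort, 8 historical comparator, 5 SCCS/SCRI), the MaxSPRT machinery
with Monte-Carlo critical values, leave-one-out empirical calibration, and
the performance metrics: type 1 error, type 2 error per effect size, and
months to 50% sensitivity.

## A worked example

The single-outcome arithmetic of one surveillance analysis — 14 cases
observed during the time-at-risk against an expected count of 3.4 from the
historic period:

```r
library(vaxeval)

rec <- estimate_irr(14, 3.4)
rec[, .(irr = exp(log_estimate), ci_lower, ci_upper, p_one_sided, llr)]
#>         irr ci_lower ci_upper p_one_sided      llr
#> 1: 4.117647 2.251156 6.908712 1.35883e-05 9.213947

cv <- critical_value(cumsum(rep(0.38, 9)), alpha = 0.05,
                     model = "poisson", mc_reps = 1e5, seed = 42)
round(c(cv$value, cv$attained_alpha), 4)
#> [1] 2.1611 0.0470
```

The incidence rate ratio is 4.12 (exact Poisson 95% CI 2.25–6.91) and the

LLR of 9.21 far exceeds the monthly-look critical value of 2.16, so this
outcome signals. Whether to believe it depends on the design's systematic
error: fitting the error model to (here, eight) negative-control estimates
and calibrating,

```r
nd <- fit_null(c(0.21, 0.35, -0.05, 0.48, 0.10, 0.02, 0.31, 0.18),
               rep(0.15, 8))
round(c(nd$mu, nd$tau), 4)
#> [1] 0.2000 0.0693
signif(calibrate_p(rec$log_estimate, rec$se, nd), 3)
#> [1] 5.54e-05
```

— still significant after accounting for the design's tendency to
overestimate (mean systematic error +0.2 on the log scale).

The full pipeline is driven by the numbered scripts under `analysis/`:

```sh
Rscript analysis/01_simulate.R      # 20,000 persons, 93 negative controls
Rscript analysis/02_run_designs.R   # all 25 variants x 3 looks, imputation,
                                    # critical values, LOO calibration
Rscript analysis/03_performance.R   # systematic error + performance tables
Rscript analysis/04_figures.R       # the four figure archetypes
```

Step 1 prints, for the default scenario:

```
Simulated 20000 persons; 3637 received 3637 vaccine doses during the campaign
(coverage 18.2%); 237,817 outpatient visits; 70,822 first-occurrence outcome
events across 93 negative-control outcomes.
```

and the later steps write per-variant summaries under `results/tables/`:
negative-control mean log estimates per look (`estimates_summary.csv`),
fitted systematic-error parameters (`systematic_error.csv`) and type 1/2
error and months-to-sensitivity before and after calibration
(`performance.csv`). On this synthetic scenario the qualitative pattern
expected from the designs' theory emerges: case-control and the historical
comparator are biased upward, the unadjusted cohort flips sign with the
comparator anchor (visit-anchored negative, random-day positive), and
SCCS/SCRI stay near the null; calibration pulls type 1 error back toward
5% (final-look p-value rule: median 0.043 across variants; sequential
MaxSPRT rule: at most 0.076). For the strongest imputed signals (RR = 4)
the historical-comparator variants reach 50% sensitivity first (month 3 of
the campaign vs month 6 for most others); at this desk scale the weaker
imputed signals (RR 1.5-2) mostly stay below 50% sensitivity within the
9-month study, so detecting them would mean accepting a higher type 1
error.

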