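---
title: "Methods: trial-based and lifetime cost-effectiveness analysis of smoking cessation aids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based and lifetime cost-effectiveness analysis of smoking cessation aids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

quitcea evaluates whether offering an e-cigarette (EC) starter kit instead
of nicotine replacement therapy (NRT) in a stop-smoking service is good
value for money from a health-service perspective. It does so in two
stages: a within-trial analysis over the 12 months of a two-arm
randomised trial, and a lifetime projection of the one-year quit-rate
advantage through a Markov cohort model. This vignette explains the
models, their assumptions, the tunable parameters and the numerical
choices, and what the packaged synthetic data can and cannot tell you.

```{r setup}
library(quitcea)
```

## The within-trial analysis

### Costing treatment delivery

Treatment cost per participant is assembled from the session and product
log: adviser time for behavioural support sessions (sessions 1-2 at 30
minutes, later sessions at 20 minutes, costed at £37/hour), products
issued on record (NRT items at per-item costs, starter kits, e-liquid),
printed materials, and a per-participant training share (£4.40 in the EC
arm, zero in the NRT arm, because advisers are assumed already trained in
behavioural support and NRT use). Only what is on record is costed. The
training share is an input constant rather than recomputed from trainer
hours, because its decomposition (trainer time per site, number of
sessions) is not recoverable from published sources; it is exposed as the
`training_cost_pp` argument. Letters of recommendation for pharmacy
supply are assumed always redeemed, so a letter's issue brings both its
print cost and the recommended product's cost into the log.

The original starter-kit unit price is not published separately from the
£20 mean product cost per EC participant; the package's default
(`ec_kit = 19.35`) reuses the demonstration-kit price, which reproduces
that mean to within a pound given the observed mix of original kits,
2016 replacement kits (£30.54) and extra liquid bottles.

### QALYs

Utilities measured at 0, 6 and 12 months are converted to
quality-adjusted life-years by the trapezium rule over the year,
`0.25·u0 + 0.5·u6 + 0.25·u12` (`qaly_auc()`). Utilities below zero
(states worse than death, floor −0.594) are accepted. Costs and QALYs
inside the 12-month window are not discounted.

### Missing data

Follow-up costs, utilities and expenses are imputed by chained equations
with predictive mean matching (`mice_pmm()`), run separately within each
arm. Design choices where the method leaves room:

* conditional models are least-squares regressions of each incomplete
  variable on all other model variables;
* each missing entry receives an **observed** value donated uniformly at
  random from the `k = 10` cases nearest in predicted mean (ties broken
  by stable ordering), so imputations never leave the observed support;
* variables are visited most-observed first, for 10 sweeps by default;
  convergence is not monitored formally;
* `m = 35` imputations by default, following the working rule that m
  should be about the highest percentage of missing data;
* quit status is never imputed: participants lost to follow-up are
  classified as continuing smokers upstream of this package.

Costs and utilities after a participant's death are zeros, not missing
(`apply_death_zeroing()`), and are therefore never imputed over.
Estimates across imputations are pooled by Rubin's rules
(`pool_rubin()`), with a t reference on the Rubin degrees of freedom.

### Incremental analysis

Incremental cost and incremental QALYs are the treatment-arm coefficients
of generalized linear regressions adjusting for the respective baseline
value (pre-trial service costs, or baseline utility), age, gender, study
site, free-prescription entitlement and baseline cigarette dependence
(`adjusted_difference()`). The default family is identity-link gaussian,
so the arm coefficient is an adjusted mean difference in pounds or QALYs;
a gamma/log family can be passed where cost skew warrants it, at the
price of losing the additive reading. The ICER is the ratio of the two
adjusted differences, classified on the cost-effectiveness plane
(`icer()`).

Uncertainty is non-parametric: participants are resampled with
replacement within arm, preserving arm sizes, and both models re-fitted
per replicate (`bootstrap_cea()`). With multiply imputed input the
replicates cycle deterministically through the completed datasets, which
folds imputation variability into the cloud without the runtime of a
full bootstrap-then-impute nesting; the latter ordering is a known
alternative and can be built from the exported pieces. The
acceptability curve (`ceac()`) is the fraction of replicates with
positive net monetary benefit `λ·ΔQALY − ΔCost` at each willingness-to-pay
threshold λ.

## The lifetime model

### Structure

`run_cohort()` projects a cohort of 1000 smokers aged 41 (52% male)
through three states — smoker, ex-smoker, dead — on annual cycles until
the cohort reaches age 90. Cycle 1 is the trial year: the cohort is
allocated by the arm's one-year quit rate (deaths, at the trial's
observed first-year rates, are removed from the quit denominator) and
accrues the arm's trial-estimated per-person cost and QALYs
undiscounted. From cycle 2 on:

1. ex-smokers relapse with annual probability 10% during cycles 2-11;
   abstinence is permanent afterwards; no new quit attempts are modelled;
2. annual smoking-attributable healthcare costs are accrued on the
   post-relapse, **pre-mortality** occupancy;
3. status-, sex- and age-band-specific mortality is applied;
4. annual utility weights are accrued on the **survivors**.

Step 2 versus step 4 is a deliberate asymmetry: people who die during a
year still generate healthcare costs in that year (much of
smoking-attributable spending is terminal-phase care), but accrue no
further quality-adjusted survival. Under the alternative convention of
zeroing both from the death cycle the incremental cost between arms
roughly doubles and the lifetime ICER moves from ≈£105 to ≈£127 per
QALY; levels change by well under 1%. There is no half-cycle correction.

Male and female sub-cohorts run separately with sex-specific inputs and
are combined at the configured male fraction (0.52, the trial's
composition; the published model states only the entry age, so the sex
handling is a package choice and configurable). Ages 41-44 use the
35-44 input band; band lookup is by attained age each cycle.

### Inputs

`lifetime_inputs()` carries the full input set, also shipped as a YAML
fixture (`inst/extdata/lifetime_inputs.yaml`): annual relapse
probability 10% (SE 3.06%) for ten years; annual mortality by sex, age
band and smoking status (ex-smoker always at or below smoker); annual
smoking-attributable healthcare costs (SE £0 — treated as fixed); annual
utility weights by the same strata (ex-smoker always at or above
smoker); first-cycle per-person costs £1116/£1174 and QALYs 0.882/0.886
(NRT/EC) with their trial SEs; quit rates 9.9%/18.0% (SE 1.4%/1.7%).
Validity checks enforce the probability ranges and the status orderings.

The annual cost inputs are *smoking-attributable* costs: the package
exposes the attributable-proportion formula
(`smoking_attributable_proportion()`) — excess risk
`p_cur(r_cur−1) + p_ex(r_ex−1)` over one plus itself — for users who
want to build such inputs from prevalence and relative risks, but the
shipped per-band values enter directly.

### Discounting

Costs are discounted at 3.5% per year beyond the first cycle, with the
factor `1/1.035^(t−1)` for cycle `t`. The default QALY discount rate is
**zero**: the package's reference lifetime results (about 24.1-24.3
QALYs per person) are only attainable undiscounted — any 3.5% QALY
discounting caps lifetime QALYs near 21 over this horizon — while the
reference lifetime costs match the discounted run. Both rates are
explicit arguments (`discount_rate_cost`, `discount_rate_qaly`), so a
fully discounted analysis is one argument away; the package treats the
split default as a property of the results it reproduces, not a
methodological recommendation.

### Probabilistic sensitivity analysis

`run_psa()` assigns beta distributions to probabilities (relapse,
mortality, and by default the quit rates, whose SEs are published) and
gamma distributions to costs and QALY weights (utilities, first-cycle
costs and QALYs), each moment-matched to its mean/SE (`moment_match()`;
zero SE means fixed). Each of the 10,000 default iterations draws one
value per parameter and runs both arms with **identical draws for every
parameter the arms share** (common random numbers); only quit rates and
first-cycle costs/QALYs are arm-specific. Parameters are drawn
independently of one another — no correlation structure is published.

The coupling choice matters more than any single distribution: with
common draws, shared-parameter uncertainty largely cancels out of the
increments, the incremental-QALY sign is driven by the two quit-rate
draws, and the acceptability probability at £20,000-£30,000/QALY comes
out near 0.98. Sampling shared parameters independently per arm instead
roughly doubles the incremental-QALY dispersion and drops that
probability towards 0.85. The package defaults to common draws — the
standard prescription for decision models, since a single true parameter
value underlies both strategies — and the acceptance suite reports the
resulting probability as is.

Because the model is non-linear in its parameters, PSA means carry a
small convexity offset from the deterministic run (about +0.5% on arm
QALYs, about +5% on the incremental QALYs, driven mainly by the convex
dependence of sustained abstinence on the relapse rate); the test suite
checks propagation consistency at relative tolerances that accommodate
this rather than pretending the offset away.

## The synthetic trial generator

`generate_trial()` exists so that every pipeline stage is exercisable
without individual-level trial data. It emulates, per arm: covariates
(log-normal age with median 41, 52% male, three sites, 0-10 dependence
scores, free-prescription entitlement), session attendance, product
logs, gamma-distributed service costs with a person-level frailty (CV of
order 4, matching the heavy right skew of service-use data, and inducing
baseline-to-follow-up cost correlation so covariate adjustment has
something to adjust for), utilities with beta marginals on [−0.594, 1]
coupled within person through a Gaussian copula, a marginal-mean-
preserving utility advantage for quitters, participant expenses, deaths
with post-death zeroing, and whole-section missingness at 6 and 12
months via a logistic model on observed baseline covariates whose
intercept is calibrated by root-finding so the marginal rate is exactly
the configured one (0.35 by default).

What it does **not** emulate: five-domain EQ-5D response patterns
(utilities are generated directly), item-level missingness (sections go
missing whole, which is the dominant observed pattern), within-person
correlation between costs and utilities (no published value exists to
calibrate against; the two are independent given arm and quit status),
and any baseline missingness. Consequently, passing recovery tests on
synthetic data show that the estimators do what they claim under the
generator's assumptions — they cannot certify behaviour under real-data
features the generator omits, most notably the unpublished
individual-level covariance structure that the trial's own bootstrap
probabilities depend on.

## Problem sizes and numerical choices

The test suite runs the generator at up to 10,000 participants per arm
for moment checks, 100 simulation replicates at 5,000 per arm for
coverage of injected effects (nominal 95% intervals are required to
cover in at least 90 of 100), a 10,000-iteration PSA, and a
20,000-person microsimulation as an independent oracle for the cohort
engine on a short horizon — sizes chosen so Monte-Carlo error is small
against the tolerances being asserted. Mass conservation in the cohort
engine is asserted to 1e−9 relative; occupancy is propagated in double
precision with no renormalisation. Beta moment-matching rejects
infeasible mean/SE pairs (`s² ≥ m(1−m)`) before any iteration runs.
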