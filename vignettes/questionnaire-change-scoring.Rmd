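---
title: "Scoring changing questionnaires for trajectory analysis: models, defaults and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring changing questionnaires for trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschtraj)
```

## What the package studies

Long-running cohorts often replace the questionnaire used to measure a
subjective phenomenon mid-follow-up. `raschtraj` implements a simulation
pipeline for a focused question: when only some items are shared across
questionnaire versions, which scoring strategy lets a latent class growth
analysis (LCGA) best recover the true trajectory groups — the raw sum over
shared items, the per-time standardised sum over all available items, or the
latent variable score from a Rasch model with item parameters constrained
equal over time?

The package is organised around five stages, each usable on its own:
simulation (`study_design()`, `simulate_cohort()`, `apply_scenario()`),
scoring (`score_raw()`, `score_standardised()`, `person_scores()`), Rasch
calibration (`estimate_difficulties()`), mixture modelling (`fit_lcga()`)
and evaluation (`match_classes()`, `evaluate_classification()`,
`aggregate_replicates()`), with `run_experiment()` orchestrating the whole
Monte Carlo design.

## The data-generating model

Responses follow a longitudinal Rasch model: subject *i*'s probability of a
positive response to binary item *j* at time *t* is
`plogis(theta_i(t) - delta_j)`. The defaults mirror a typical developmental
cohort:

* **T = 4 collection times, J = 10 binary items**, three trajectory groups of
  **1000 subjects** each (N = 3000): a stable low group (latent mean −1 at
  every time), a stable high group (+1), and an increasing group rising
  linearly from −0.5 to 1.
* **Latent covariance** shared by all groups: variance 0.3 at every time;
  correlations 0.8 at lag 1, 0.7 at lag 2, 0.6 at lag 3 — the magnitude of
  tracking one sees in repeated internalising-symptom measurements in
  childhood cohorts. `study_design()` validates positive definiteness and
  rejects impossible correlation patterns.
* **Item difficulties** `delta_j = qnorm(j / (J + 1))`: evenly spaced normal
  percentiles, symmetric about zero. For J = 10 this puts the three easiest
  items at −1.34, −0.91, −0.60 and the three hardest at 0.60, 0.91, 1.34, so
  the "seven difficult" shared set spans [−0.60, 1.34] and its mirror spans
  [−1.34, 0.60]. An explicit difficulty vector can be supplied instead.

### Item-sharing scenarios

A `scenario_mask()` erases chosen items at chosen times, emulating a
questionnaire change. The built-ins for the 10-item bank are `complete`
(nothing erased), `seven_difficult` (easy items 1, 2, 4 erased),
`seven_easy` (the mirror, items 7, 9, 10) and `four_items` (the union,
leaving the four mid-difficulty items 3, 5, 6, 8 shared). The erased
*times* default to 3 and 4 — a single questionnaire change after the second
wave. The exact erased-time pattern is a modelling choice, not something the
shared-item counts pin down, so it is fully configurable per (item, time)
pair; the raw score provably depends only on which items are *ever* erased,
and the mask is recorded in every design and run log. Within a replicate all
scenario arms are applied to copies of the *same* simulated cohort, so
differences between arms are purely due to the masking.

### What the generator does and does not emulate

The simulator reproduces the features that drive the scoring comparison:
binary items of realistic difficulty spread, strong but imperfect latent
tracking, group-structured trajectories, and designed (all-subject)
missingness of items at times. It does **not** emulate polytomous items,
differential item functioning or time-varying difficulties (longitudinal
measurement invariance is assumed by construction), person-level item
nonresponse, informative dropout, or covariates. Conclusions from passing
tests therefore speak to the relative behaviour of the scoring strategies
under a clean Rasch world; real questionnaires that violate unidimensionality
or invariance can behave differently.

## The three measures

* **Raw score**: sum over the shared set from `shared_items()` — items with
  no designed missingness anywhere. Integer in [0, #shared].
* **Standardised score**: per time, the sum over all items observed at that
  time, centred and scaled by that time's sample mean and SD (denominator
  N − 1; the choice is immaterial at N = 3000 and stated for
  reproducibility). Standardisation statistics are recomputed on each
  analysis sample, per replicate. The per-time centring encodes the
  assumption of a stable population mean over time — exactly the assumption
  that hurts this measure for the increasing group.
* **Latent variable score**: a two-step Rasch procedure. First,
  `estimate_difficulties()` pools every subject × time record into one
  calibration, which *is* the across-time equality constraint: one difficulty
  per item regardless of time. The default estimator is conditional maximum
  likelihood (CML) — conditioning on each record's raw score eliminates the
  person parameters, so no assumption about the (here, mixture-shaped)
  latent distribution is needed. Newton–Raphson on the sum-to-zero
  parametrisation, gradient tolerance 1e-8, at most 100 iterations, with
  step halving; elementary symmetric functions are computed by the stable
  summation recursion. Marginal ML (normal latent, 21-node Gauss–Hermite
  quadrature) is available as a cross-check and agrees with CML within
  sampling error on the default design. Second, `person_scores()` maps each
  subject-time's raw score over its observed item set to a latent estimate.
  The default is the expected a posteriori (EAP) score — the posterior mean
  under a per-time normal prior whose mean and variance are themselves
  estimated by marginal ML with the difficulties held fixed. EAP is the
  factor score that maximum-likelihood IRT software reports for categorical
  items, i.e. the estimate the applied workflow this package emulates
  actually produces, and it is finite at all-zero and all-correct records
  (common at N = 3000). Warm's weighted likelihood estimate (WLE; less
  shrinkage, no prior to misspecify — relevant because the true latent
  distribution is a 3-component mixture, not a normal) and plain ML are
  selectable; ML refuses perfect scores with a pointed error. The choice is
  consequential: WLE stretches the extreme raw scores far into the tails,
  which inflates the within-class residual spread and costs the downstream
  classification about two percentage points relative to EAP in the complete
  scenario.

The two-step design (calibrate difficulties, score persons, then fit LCGA to
the scores) matches the applied workflow the package studies — difficulties
*concurrently estimated* from the same data, which is also why the latent
variable score carries more estimation noise than one might expect. A
one-step joint mixture-measurement model would be a different (and stronger)
procedure and is deliberately out of scope.

## The LCGA

`fit_lcga()` maximises the observed-data likelihood of a K-class mixture of
linear growth curves by EM:

* **Time codes 0, 1, 2, 3** (intercept = first-wave level). The coding
  affects the reported intercept/slope, never the classification.
* **Residual variances**: time-specific and class-invariant by default (the
  usual growth-model convention); a constant-variance option exists.
* **Starts**: 20 by default — one k-means partition of the subject score
  vectors plus random responsibility draws; the best converged start wins.
  On these well-separated three-group data the k-means start almost always
  finds the optimum, which is why the heavy Monte Carlo runs use 5 starts
  (see below).
* **Convergence**: relative log-likelihood change below 1e-7, at most 500
  iterations; the per-iteration log-likelihood trace is stored on the fit so
  monotonicity is checkable, and a degenerate class (weight < 1/N) is
  flagged rather than fatal.
* **Label order**: classes are sorted by ascending mean fitted trajectory,
  making "low / increasing / high" deterministic; modal assignment breaks
  posterior ties toward the lower class index.

Classifications are compared with the simulated groups after exhaustive
permutation matching (maximal diagonal agreement over all 3! relabellings),
and summarised by %CC (overall and per group), Cohen's kappa and relative
entropy `1 − Σ −p·ln p / (N ln K)`. Replicate means carry
normal-approximation 95% CIs (`1.96·sd/√R`, the same arithmetic that sizes
the number of replicates: an SD of 0.011 at R = 200 gives ±0.15 percentage
points on a proportion).

## A known and deliberate limitation

LCGA's working model treats scores as independent over time given the class,
but the generating latent covariance has lag correlations up to 0.8. Under
this misspecification the maximum-likelihood component means are pushed
apart from the generating group means by roughly 0.2–0.3 on the latent
scale — verifiably the ML answer, since the fitted working-model likelihood
exceeds the likelihood evaluated at the generating parameters. The
*classification* criteria are barely affected (the decision boundaries move
little), which is why the package's Monte Carlo reproductions target the
classification criteria; exact component-mean recovery should not be
expected from LCGA on data with strong within-class tracking, and the test
suite asserts the qualitative structure (flat/rising/flat, near-equal
weights) rather than a tight numeric match on the means.

Two further numerical notes. First, in the complete scenario the raw and
standardised scores are per-time affine transforms of one another, but the
per-time scale factors differ slightly (sampling variation of the per-time
SDs), so the two classifications agree on ~99.8% of subjects rather than
100%. Second, the latent-variable-score arm is sensitive to estimator
details (CML + WLE here; other software uses other estimators and factor
scores), so its reproduction tolerances are wider than those of the sum
scores.

## Problem sizes used by the tests and the acceptance script

The Monte Carlo reproductions use 200 replicates for the benchmark arm
(LCGA on the simulated latent values — the ceiling of what LCGA can do
when measurement error is removed) and 50 replicates for the item-based
measure arms, with 5 EM starts per fit; at these sizes the Monte Carlo
standard errors are several times smaller than the reproduction tolerances.
Unit tests run on cohorts of 40–80 subjects per group, with full-size
(N = 3000) single cohorts for the parameter-recovery and invariance checks.

```{r example, eval = FALSE}
res <- run_experiment(experiment_config(n_replicates = 200, seed = 1))
format_table1(res$summary)
autoplot(res)
```
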