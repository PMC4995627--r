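# raschtraj

Scoring changing questionnaires for trajectory analysis in long-term cohort
studies.

## The problem

Cohorts followed for decades rarely keep the same questionnaire: items are
dropped, added or reworded as instruments improve or as the construct is
expressed differently across developmental stages. When the measure of a
subjective phenomenon (anxiety, internalising symptoms, quality of life, ...)
is a sum of item responses, a questionnaire change breaks the comparability
of scores over time. Three strategies are commonly used to restore a
comparable measure:

* the **raw score** `S(t)` — the plain sum over the items *shared by every
  questionnaire version*, discarding everything else;
* the **standardised score** `stS(t)` — the sum over *all* items available at
  time *t*, centred and scaled by that time's sample mean and SD (which
  implicitly assumes the population mean is stable over time);
* the **latent variable score** `θest(t)` — the person level estimated under
  a Rasch measurement model with item difficulties constrained equal across
  times, so that all questionnaire versions are expressed on one latent
  scale.

`raschtraj` implements a complete Monte Carlo pipeline for comparing these
strategies by how well a downstream longitudinal analysis — Latent Class
Growth Analysis (LCGA) — recovers known trajectory groups under configurable
item-sharing scenarios.

## The models

Binary responses are generated from a longitudinal Rasch model,

    P(Y_ij(t) = 1 | θ_i(t), δ_j) = exp(θ_i(t) − δ_j) / (1 + exp(θ_i(t) − δ_j))

with person levels `θ_i = (θ_i(1), ..., θ_i(T))` drawn from a multivariate
normal whose mean trajectory depends on the subject's group (stable-low,
stable-high, increasing) and whose covariance (variance 0.3, lag correlations
0.8/0.7/0.6) is shared across groups. Item difficulties `δ_j` are
time-invariant percentiles of a standard normal.

Each score matrix is analysed with a 3-class linear LCGA,

    y_it | class k  ~  Normal(In_k + Sl_k · t,  σ²_t),

a finite mixture of linear growth curves with zero within-class growth-factor
variance, fitted by multi-start EM. Classification quality against the
simulated groups is summarised by the percentage of correctly classified
subjects (after permutation matching of class labels), Cohen's kappa and the
relative entropy of the posterior classification.

Item difficulties are estimated by conditional maximum likelihood on pooled
subject-by-time records (elementary-symmetric-function recursions,
Newton-Raphson, sum-to-zero anchoring; marginal ML with Gauss-Hermite
quadrature as an alternative), and person levels by Warm's weighted
likelihood estimator (EAP and ML available).

## Worked example

Simulate a 600-subject cohort (three trajectory groups of 200), erase six
items at the last two collection times (the "4 items" scenario), score it
with the per-time standardised score and fit the LCGA:

```r
library(raschtraj)

design <- study_design(groups = default_trajectory_groups(size = 200))
cohort <- simulate_cohort(design, seed = 42)

fit <- fit_lcga(score_standardised(apply_scenario(cohort, "four_items")),
                n_starts = 5, seed = 42)
tidy(fit)
#>   class weight intercept   slope
#> 1     1  0.291    -0.833 -0.0604
#> 2     2  0.350    -0.281  0.163
#> 3     3  0.358     0.950 -0.110

evaluate_classification(assign_classes(fit), cohort$group, fit)
#>     pcc kappa entropy
#> 1  74.8 0.622   0.680
```

The three fitted classes line up with the low, increasing and high groups
(ascending order); 74.8% of subjects are assigned to their true group, kappa
0.622 indicates substantial agreement, and the relative entropy of 0.680
says the posterior classification is moderately crisp. Per-group accuracy
(`evaluate_classification(...)$group_pcc`) shows the usual pattern: the
increasing group (67.5%) is harder to pick out than the stable ones.

A full experiment — R replicate cohorts, every scenario arm applied to a
copy of the same cohort, every measure scored and fitted — is one call:

```r
res <- run_experiment(experiment_config(n_replicates = 200, seed = 1),
                      out_dir = "results")
res$summary        # tidy means with 95% CIs per criterion x scenario x measure
autoplot(res)      # per-group accuracy by scenario and measure
```

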