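# socialdisc

`socialdisc` is a tidy R pipeline for analysing **social discounting**
tasks: experiments in which a participant repeatedly chooses between
keeping money and splitting it with a real person at one of seven social
distances (N = 1, 2, 5, 10, 20, 50, 100 — the rank of that person on an
imagined closeness list). It was built for studies comparing
high-psychopathy and control groups — where the scientific questions are
whether devaluation of others' outcomes is steeper in high-psychopathy
adults and whether that devaluation statistically accounts for their
antisocial behaviour — but every stage is a general-purpose tool.

The pipeline covers, end to end:

* **Task encoding and extraction** — the canonical 7 × 9 trial schedule
  ($155 → $75 selfish amounts in $10 steps vs a $75/$75 split),
  indifference points from binary choice vectors (censored at $75/$155,
  non-monotone blocks flagged), and amounts willing to forgo
  v = indifference − 75.
* **Discounting models** — per-participant and pooled nonlinear
  least-squares fits of the hyperbolic model

  $$v = \frac{V_0}{1 + kN}$$

  plus exponential ($V_0 e^{-kN}$) and linear ($\max(V_0 - kN, 0)$)
  alternatives; AIC model selection with Δ AIC and Akaike weights
  $w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$; logk = ln k; and the
  model-agnostic trapezoidal AUC normalised to [0, 1].
* **Inference** — Welch t-tests with Cohen's d, chi-squared tests,
  multiple regression with fully standardized coefficients ("Std. B":
  every variable z-scored, including binary indicators), moderation,
  covariate-adjusted odds ratios, Bonferroni thresholds.
* **Mediation** — a simulation-based engine (quasi-Bayesian parameter
  draws or bootstrap) reporting ACME, ADE, total effect and proportion
  mediated with percentile CIs and simulation p-values.
* **Reliability & robustness** — Cronbach's α, one-way random-effects
  ICC(1,1), 10-fold cross-validation, greedy caliper propensity-score
  matching with SMD balance tables.
* **Synthetic cohorts** — a generator that emulates the statistical
  structure this analysis assumes (group-separated TriPM distributions, a
  latent logk driving choices through the hyperbolic rule, an antisocial
  behaviour outcome partially mediated by logk), so the full pipeline is
  testable with no external data.

## Worked example

```r
library(socialdisc)

bundle <- run_pipeline(run_config(
  cohort = cohort_config(n_control = 150, n_high = 100, seed = 3),
  mediation_sims = 500))
bundle
#> <sd_result_bundle>
#>   participants analysed: 244
#>   best-fitting family (pooled AIC): hyperbolic
#>   akaike weights: hyperbolic=1.000 exponential=0.000 linear=0.000
#>   mean logk: -3.563; mean AUC: 0.452
#>   group difference in logk: t(226.07) = -6.11, d = -0.77
```

Six of the 250 generated participants failed two or more attention checks
and were excluded. The pooled fit across all retained (N, v) observations
prefers the hyperbolic family outright (Akaike weight 1.000), and the
high-psychopathy group discounts more steeply: its mean logk is higher, a
standardized difference of d = −0.77 (control minus high) here.

The group regression with covariates keeps the study-style table layout —
unstandardized b with CI, fully standardized Std. B with CI, and p:

```r
tidy(bundle$regressions$group_logk)
#> # A tibble: 6 × 10
#>   term                       b     se  ci_low ci_high     std_b std_se ...
#> 1 (Intercept)        -4.47     0.711  -5.87   -3.07   -6.79e-17 0.0604
#> 2 group_high          1.63     0.310   1.02    2.24    3.52e- 1 0.0669
#> 3 age                -0.000162 0.0135 -0.0268  0.0265 -7.95e- 4 0.0666
#> 4 gender             -0.0858   0.280  -0.638   0.466  -1.87e- 2 0.0610
#> 5 income_bracket      0.0244   0.0746 -0.123   0.171   2.04e- 2 0.0626
#> 6 fluid_intelligence  0.0424   0.0678 -0.0911  0.176   3.91e- 2 0.0624
```

The group term (b = 1.63, Std. B = 0.35, p < 0.001) recovers the planted
effect; the intercept's Std. B is 0 by construction on the z-scale.
Mediation of the group difference in antisocial behaviour through logk:

```r
tidy(bundle$mediation$group)
#> # A tibble: 4 × 5
#>   effect        estimate   ci_low ci_high     p
#> 1 acme            1.33   -0.211    3.04   0.104
#> 2 ade            38.1    32.4     43.6    0.004
#> 3 total          39.4    34.2     44.4    0.004
#> 4 prop_mediated   0.0325 -0.00546  0.0812 0.104
```

The indirect path through discounting is ~3% of the total effect at this
desk-scale n (the generator plants ~4%; at n = 244 the ACME interval still
brushes zero). `acme + ade = total` holds exactly by construction.
`plot_discount_curve()` and `autoplot()` methods draw the group mean
discounting curves and mediation effect intervals.

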