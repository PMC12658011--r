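---
title: "Methods: from binary sharing choices to discounting, inference and mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from binary sharing choices to discounting, inference and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialdisc)
```

## The task and its measurement model

The social discounting task asks a respondent to imagine a list of 100
people ranked by closeness, name the people at ranks N = 1, 2, 5, 10, 20,
50 and 100, and then make nine dichotomous choices per person: keep an
amount for themselves (from $155 down to $75 in $10 steps) or split the
money so that both they and the named person receive $75. Choosing
generously on the $155 trial sacrifices $80; on the $75 trial it sacrifices
nothing. The *indifference point* for a distance is the selfish amount at
the trial where the respondent switches from keeping to sharing, censored
at $75 (never shares) and $155 (always shares). The *amount willing to
forgo* is v = indifference − 75, in [0, 80].

Two decisions close gaps the task definition leaves open:

* **Non-monotone blocks.** A respondent may return to selfish choices
  after first sharing. The switch rule only defines the monotone case, so
  we take the *first* selfish-to-generous switch and raise a
  `violation` flag; flagged blocks are counted and retained, since no
  exclusion rule exists for them. For monotone blocks the extraction
  satisfies indifference = max(75, 65 + 10 g) where g is the number of
  generous choices — the test suite checks this against an exhaustive scan
  of all 2^9 = 512 choice vectors.
* **Switch-trial value, not midpoint.** The indifference point is the
  selfish amount *at* the switch trial, matching the $75/$155 censoring
  endpoints, which are trial values rather than midpoints.

## Discounting models

Generosity declines with social distance following the hyperbolic value
function

$$v = \frac{V_0}{1 + kN},$$

with alternatives v = V0 e^{-kN} (exponential) and v = max(V0 − kN, 0)
(linear) considered for model selection. Parameters that matter:

* **V0** (dollars): the undiscounted value. Its treatment in published
  analyses is ambiguous, so both modes are provided; the default estimates
  V0 freely in (0, 160], and `fit_options(v0_mode = "fixed")` pins it.
* **k** (per unit distance) and **logk = ln k**: the discount rate. k is
  bounded in [10⁻⁶, 10³]; the floor keeps logk finite for people who never
  discount (flagged `k_floored`), and all-zero profiles run to the upper
  bound and are flagged `degenerate`.
* **AIC** uses the Gaussian profile-likelihood form n ln(rss/n) + 2p with
  the additive constant dropped; it is shared by every family, so
  within-dataset comparisons are unaffected. AICc is available via
  `fit_options(use_aicc = TRUE)`. Akaike weights are
  exp(−Δᵢ/2)/Σⱼexp(−Δⱼ/2).

Numerically, fitting is bounded least squares over (V0, ln k) — the log
scale keeps the two parameters comparably conditioned — with five
multistarts of k log-spaced in [10⁻⁴, 1], a polish pass from the best
start, and ties broken toward smaller k. The suite cross-checks fits
against a dense 600-point grid-search oracle and requires exact recovery on
noiseless profiles.

The model-agnostic **AUC** is the trapezoidal area of v against N over the
seven observed distances, normalised by (99 × 80) so it lies in [0, 1]. No
synthetic N = 0 anchor is added because the analysis uses only the seven
observations. Higher logk means steeper discounting; higher AUC means more
overall generosity; the pipeline always reports both (a small multiverse
over the discounting metric).

## The synthetic cohort

`cohort_config()` encodes the study conditions the analysis targets, and
its defaults are fixed once from those conditions:

* group sizes 427 controls / 288 high-psychopathy;
* TriPM totals N(55.86, 19.90²) and N(122.25, 16.92²) by group, with
  boldness/meanness/disinhibition generated as configurable shares of the
  total plus zero-sum noise (so subscales sum exactly to the total; only
  totals and subscale totals are modelled, never items);
* latent logk N(−4.5, 1.65²) and N(−3.0, 1.65²): a standardized group
  difference of 1.5/1.65 ≈ 0.91, matching the magnitude such samples
  report. These means put k between roughly 0.01 and 0.05, giving curves
  that span the observable v range across N = 1..100;
* STAB antisociality = 63.3 + 35.0·[high] + 1.0·logk + N(0, 18²), chosen
  so group STAB moments land near 58.8 (18.1) / 95.3 (18.7) and the
  planted indirect path (1.5 × 1.0) is about 4% of the total group effect
  — the proportion-mediated regime of interest. Setting the logk
  coefficient to 0 removes the indirect path, which the mediation tests
  exploit as a null calibration;
* covariates (age, gender, income bracket with a "don't know" mass, fluid
  intelligence 0–13, attention-check failures) drawn from the per-group
  empirical distributions of the same sample descriptions.

Choices are simulated from each participant's latent logk with a logistic
response rule: P(generous) = logistic((v_N − forgone)/τ) with temperature
τ in dollars (default $2, enough noise to blur the grid without destroying
the curve). τ = 0 is deterministic threshold responding, under which the
extracted v equals 10·⌊v_N/10⌋ — the nine-trial $10 grid censors the
latent curve, so latent k is reproduced *exactly* end-to-end only when
every v_N lies on the grid; the tests assert exact grid-floor agreement for
arbitrary k and exact k recovery on noiseless continuous profiles.

What the generator does **not** emulate: item-level responding,
recruitment-source differences, heavy-tailed or bimodal rate
distributions, within-person drift across blocks, and any dependence of
response noise on distance. Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes, not that real cohorts satisfy
those assumptions.

Group assignment uses gender-specific TriPM cutoffs (score ≥ cutoff →
high; the boundary score itself is high because only those who *fall
below* a cutoff are moved out). The default cutoffs — male 105,
female/other 91 — are placeholder estimates read off the within-group score
ranges such samples print; published percentile norms should replace them
when available. "Other" gender uses the female/other cutoff, matching how
reassignment counts are pooled. Attention exclusions drop participants
failing ≥ 2 of 4 checks; "don't know" income is recoded to the round-half-up
mean bracket of the known responses.

## Inference conventions

* **"Std. B"**: every variable — outcome, continuous predictors, *and*
  binary indicators (group, gender) — is z-scored before the standardized
  fit. This is the convention under which a binary group term can show
  b = 1.56 but Std. B = 0.38 in the same row.
* Gender is coded male vs female/other with female/other the reference;
  income enters models as the ordinal numeric bracket (1–8).
* Welch t-tests (fractional df) with Cohen's d from the pooled SD; the d
  CI uses the normal approximation, the common default when the original
  CI method is unstated.
* Chi-squared tests are Pearson without continuity correction (tables are
  large).
* Moderation enters the product of the two z-scored variables as its own
  term; odds ratios come from maximum-likelihood logistic regression with
  Wald CIs; all tests are two-tailed; Bonferroni thresholds are α/m.

## Mediation engine

The mediator model (mediator ~ treatment + covariates) and outcome model
(outcome ~ treatment + mediator + covariates) are fitted on the same rows;
with no treatment–mediator interaction the ACME is a·b·(t1−t0) and the ADE
is c′·(t1−t0) per parameter draw. The default quasi-Bayesian method draws
1000 parameter vectors from each model's asymptotic multivariate normal; a
row-resampling bootstrap is available. Point estimates are draw means, so
acme + ade = total holds identically; CIs are percentile; p-values are
2·min(P(draw ≤ 0), P(draw ≥ 0)) floored at 2/sims. The proportion mediated
is the median of acme/total across draws because the ratio is heavy-tailed,
and it reports the ACME p-value, whose sign it tracks whenever the total
effect is bounded away from zero. The binary treatment contrast is 0→1;
continuous treatments use mean ± 1 SD. Sims count and CI method are
surfaced in the result metadata since the original choices are unstated.

## Reliability and robustness

Cronbach's α = (m/(m−1))(1 − Σ item var / var of sums) with a Feldt F CI.
ICC(1,1) — single rater, absolute agreement, one-way random effects — is
(MSB − MSW)/(MSB + (k−1)MSW) with the standard F bounds. Cross-validation
uses a seed-deterministic partition into folds differing by ≤ 1 row and
reports per-fold coefficients plus pooled out-of-fold R². Propensity
matching is greedy 1:1 nearest-neighbour on the logit propensity score,
without replacement, caliper 0.2 logit-PS SDs — the most common
convention, since the original specification is not printed — matching the
hardest (highest-propensity) treated units first with ties broken by id.
Balance is reported as standardized mean differences against the pre-match
pooled SD.

## Problem sizes and numerical checks

The test suite runs everything at desk scale: cohorts of 50–270
participants, 100-replicate family-selection simulations with 15
participants each, 200-replicate mediation coverage at n = 150 with 150
draws, and noise σ ∈ {0, 2, 5} dollars for recovery studies. The
family-selection simulations use mild between-participant rate
heterogeneity (±25% around the family's rate): under strong heterogeneity
a pooled mixture of clipped linear or exponential curves genuinely
approximates a hyperbola, so family identification fails for
identifiability reasons rather than implementation ones.

Known limitations: per-participant fits use seven observations, so k for
extreme non-discounters/discounters is boundary-limited by design (and
flagged); the mediation engine covers the linear no-interaction case only;
matching implements the greedy algorithm, not optimal matching; and the
synthetic generator's Gaussian latent structure is a deliberate
simplification of real cohorts.

## A minimal run

```{r, eval = FALSE}
bundle <- run_pipeline(run_config(
  cohort = cohort_config(n_control = 150, n_high = 100, seed = 3),
  mediation_sims = 500))
bundle
tidy(bundle$regressions$group_logk)
tidy(bundle$mediation$group)
autoplot(generate_cohort(cohort_config(n_control = 50, n_high = 50)))
```
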