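---
title: "Exposome scores and mixed graphical model networks: methods"
author: "exponet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exposome scores and mixed graphical model networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exponet)
```

## The scientific problem

Cumulative environmental risk — winter season of birth, obstetric
complications, advanced paternal age, non-right-handedness, childhood
trauma, problematic cannabis use, urban upbringing — is increasingly
studied as a single *exposome score* (ES) rather than as isolated
exposures. `exponet` implements a complete, testable pipeline for the
standard analysis that links such a score to multiple psychopathology
domains (depressive, anxiety, manic, ADHD, obsessive-compulsive symptoms
and psychotic-like experiences, measured by the PHQ-9, GAD-7, MDQ, ASRS-5,
OCI-R and PQ-16 sum-scores) through a regularized partial-association
network. Because participant-level survey data of this kind are rarely
public, the package also ships a synthetic-cohort generator calibrated to
published sample marginals, and a Gibbs sampler for known mixed graphical
models, so every stage can be exercised and validated end to end.

## The exposome score

Each of the ten exposure components is binarized from raw survey answers
(see `binarize_exposures()` for the exact rules) and weighted by the
natural logarithm of a meta-analytic odds ratio:

$$\mathrm{ES}_i = \frac{1}{K} \sum_{k=1}^{10} x_{ik}\,\ln \mathrm{OR}_k,$$

where $x_{ik} \in \{0,1\}$ indicates presence of component $k$. Advanced
paternal age carries two weight tiers (35-54 years: OR 1.28; at least 55
years: OR 2.22), of which a respondent contributes at most one.

Two denominator policies are implemented because the phrase "divided by
the number of exposures" is ambiguous when components are missing:

* `fixed_total` (default): $K = 10$ always; missing components contribute
  zero. Under this policy the analytic mean score for the published sample
  prevalences, $\sum_k p_k \ln \mathrm{OR}_k / 10 \approx 0.245$,
  reproduces the published mean of 0.25, which is why it is the default.
* `per_respondent_recorded`: $K$ is the respondent's count of non-missing
  components; a respondent with all components missing has no defined
  score and is an error.

Obstetric "I don't know" answers follow an affirmative-dominates rule: any
"yes" makes the component present; otherwise any "I don't know" makes it
missing. This respects the convention that uncertainty is missing data
without discarding positive reports. The four childhood-trauma screens are
scored as four separately weighted components, since four distinct odds
ratios are published for them.

```{r es-example}
w <- default_weight_table()
r <- data.frame(respondent_id = 1, birth_month = 1, oc_csection = "no",
                oc_low_birth_weight = "no", oc_preterm = "no",
                paternal_age = 40, handedness = "right",
                emotional_neglect = "no", emotional_abuse = "yes",
                bullying = "no", sexual_abuse = "no")
for (i in 1:11) r[[sprintf("cpq_%02d", i)]] <- "no"
r$residence <- "rural"
compute_es(binarize_exposures(r), w)[, 1:3]
```

## The synthetic cohort generator

`generate_cohort()` draws raw answers — months, yes/no/"I don't know"
items, paternal age in years, residence categories — such that downstream
binarization reproduces requested prevalences in expectation. Defaults are
the published characteristics of a non-clinical web-survey sample of 1100
Polish adults aged 18-35 (e.g. emotional neglect 52.4%, urban upbringing
61.1%, PHQ-9 9.4 ± 6.2, obstetric-complication missingness 21.5%).

Calibration choices worth knowing:

* **Symptom scores** are sampled from a latent Gaussian, rounded to
  integers and clipped to the instrument range (PQ-16 0-16, GAD-7 0-21,
  PHQ-9 0-27, MDQ 0-13, OCI-R 0-72, ASRS-5 0-24). Clipping inflates the
  mean (for the OCI-R by about +0.4 at the default marginals), so the
  latent mean is solved from the censored-normal closed form so the
  *post-clipping* mean lands on target. The SD is left at the latent
  value; censoring shrinks it slightly. Only mean ± SD are published, so
  no shape beyond this is claimed.
* **Paternal age** is a truncated normal on 16-70 years with SD 6; its
  mean is solved so that the share of integer ages ≥ 35 equals the
  requested prevalence (24.8% by default). Both weight tiers can occur.
* **Month of birth** is uniform within winter (December-February) and
  within the other nine months, re-weighted so the winter share hits its
  target (24.5%, close to the uniform 3/12).
* **Any-of-k items** (three obstetric questions, eleven cannabis-problem
  items) use a per-item "yes" probability of
  $1 - (1 - p)^{1/k}$ so the *any-yes* rate equals the target.
* **Missingness is MCAR**: a missing obstetric record sets all three items
  to "I don't know"; a missing paternal age becomes an empty cell. The
  published counts say nothing about the mechanism, so nothing more
  elaborate is emulated.
* Exposures and symptoms are generated **independently** by default; the
  published data carry unknown dependence (e.g. trauma co-occurrence), so
  dependence is never asserted. To impose a *known* dependence structure,
  `inject_dependence()` re-samples the node columns from a user-specified
  mixed graphical model whose thresholds and conditional variances are
  calibrated by damped stochastic approximation to preserve the original
  marginals (prevalence drift ≲ 2 points, mean drift ≲ 5%).

What passing tests on these cohorts show — and do not show: they validate
the pipeline's arithmetic, calibration and recovery behaviour under the
stated generating family. They cannot validate distributional quirks of
real survey data (skewed sum-scores, informative missingness, item-level
structure), which the generator deliberately does not model.

## The mixed graphical model estimator

The network is a pairwise Markov random field over continuous nodes
(symptom scores, ES, age) and binary nodes (education higher vs. other,
gender, employment employed vs. unemployed; students are grouped with the
unemployed side of that dichotomy). Estimation is nodewise: each node is
regressed on all others with an L1 penalty — linear regression for
continuous nodes, logistic for binary — by cyclic coordinate descent with
Gram-matrix (covariance) updating, warm starts along the path, and
convergence tolerance 1e-7. Continuous variables are standardized to mean
0 / unit variance; binary variables stay 0/1; the intercept is never
penalized. The solvers are cross-checked against an independent lasso
implementation in the test suite.

The penalty for each node is chosen by the extended BIC,
$$\mathrm{EBIC}_\gamma(\lambda) = -2\,\hat\ell + \mathrm{df}\ln n +
2\gamma\,\mathrm{df}\ln(p-1),$$
with $\gamma = 0.25$ (the convention of the mixed-graphical-model software
family), df the number of non-zero coefficients, over a 50-point
log-spaced grid from $\lambda_{\max}$ (the smallest value that zeroes all
coefficients) down to $0.01\,\lambda_{\max}$. Ties are broken toward the
smallest $\lambda$ among minimizers. $\gamma$, the grid size and the span
are all arguments.

The two directed coefficients per node pair are combined with the
conservative **AND rule** by default (an edge exists only if both
coefficients are non-zero; `rule = "OR"` is available), with magnitude
`mean(|b_jk|, |b_kj|)` on the standardized scale and the common sign
(undefined if the two disagree). Since the selection criterion, the
AND/OR choice and $\gamma$ are conventions rather than published facts of
any particular analysis, they are recorded in the run manifest.

**Predictability** is an absolute per-node fit measure from an unpenalized
refit on the selected neighbors: $R^2$ for continuous nodes; for binary
nodes the normalized accuracy $(\mathrm{acc} - \mathrm{maj})/(1 -
\mathrm{maj})$, floored at zero, where maj is the majority-class rate.
The published notion of "proportion of variance" does not distinguish node
types; normalized accuracy is the interpretable binary analogue and is
labelled as such in outputs.

Missing data are handled by listwise deletion over the network variables,
with the dropped count reported — the conventional, if blunt, policy of
this analysis family.

```{r estimate-example}
g <- true_graph(c("x", "y", "z"), rep("continuous", 3),
                matrix(c(0, .35, 0, .35, 0, .3, 0, .3, 0), 3))
d <- sample_mgm(g, 800, burn_in = 300, thin = 2, seed = 1)
net <- estimate_network(d)
net
round(net$weights, 3)
```

## Strength, summaries, bootstraps

Strength centrality is the sum of absolute edge weights at a node; an
11-node network has 55 possible edges and summaries report the non-zero
count and percentage (rounded half-up to one decimal, matching the usual
reporting format). The packaged example network (`example_network()`), a
previously reported exposome-psychopathology network for a non-clinical
sample of 1100 adults, reproduces 22/55 non-zero edges (40.0%), with
depressive symptoms the strongest node (0.904) and the ES among the
weakest (0.481).

Stability follows the bootstrap conventions of psychometric network
analysis:

* **Non-parametric bootstrap** (`nonparametric_boot()`): respondents are
  resampled with replacement, the whole network re-estimated per
  iteration, and edge-weight and strength distributions retained.
  Resamples that turn a column constant are skipped and logged, never
  imputed.
* **Case-drop bootstrap** (`casedrop_boot()`): for each drop proportion in
  {0.05, ..., 0.75}, subsamples without replacement are re-estimated and
  their strength vectors correlated (Pearson) with the full-sample
  strengths.
* **CS-coefficient** (`cs_coefficient()`): the largest drop proportion at
  which at least 95% of iterations correlate ≥ 0.7 with the full sample;
  values above 0.25 are conventionally acceptable and the result object
  carries that flag.
* **Difference tests** (`difference_test()`): two edges or strengths
  differ significantly when the two-sided percentile interval of their
  per-iteration difference excludes zero. Percentile (not BCa) intervals
  are used, matching common practice of this toolchain; fewer than 100
  retained iterations attaches a precision warning.

Per-iteration seeds are derived from the run seed by a counter scheme, so
iteration `i` draws the same resample regardless of execution order.
Default iteration counts are B = 1000; the test suite and the acceptance
script run B = 200 and proportionally scaled replicate counts, which is
ample for the coarse rates they assert.

## Numerical choices and degenerate inputs

* Coordinate descent tolerance 1e-7 (max absolute parameter change);
  logistic IRLS weights floored at 1e-6 to avoid division blow-ups at
  fitted probabilities near 0/1.
* A lambda at or above $\lambda_{\max}$ returns the empty model exactly;
  `lambda < 0` is a validation error; non-convergence raises an error with
  the iteration count rather than returning a dubious fit.
* Zero-variance continuous nodes cannot be standardized and are an error
  at estimation; zero-variance binary nodes yield undefined (flagged)
  predictability.
* The Gibbs sampler validates that the continuous-block precision
  (diag(1/sigma^2) - W) is positive definite before sampling; an improper
  model is an error naming a continuous node rather than a silently
  divergent chain. Burn-in defaults to 1000 sweeps with thinning 10 —
  conservative for graphs up to ~20 nodes.
* The generator's calibration solves are closed-form censored/truncated
  normal expressions passed to `uniroot` at tolerance 1e-9.

## Problem sizes used in validation

The packaged tests and `scripts/acceptance.R` use: cohorts of 50,000 to
100,000 respondents for marginal calibration (prevalences within ±0.01,
means within ±0.2); n = 2000 samples from the 11-node ground-truth graph
across 20 seeds for recovery (observed sensitivity ~1.0, false-positive
rate ~0.01); 30-50 seeds of independent n = 1100 data for null
calibration (mean ~1 spurious edge of 55); and 20 replicates of B = 200
bootstraps for the difference-test operating characteristics. These sizes
were chosen so each assertion's Monte-Carlo error is comfortably below the
tolerance it checks.

## Known limitations

* Only binary and Gaussian-conditional nodes; no categorical (>2 level),
  Poisson, moderated or time-varying models.
* The generator produces sum-scores only, not item-level responses, and
  its independence default understates real-world exposure co-occurrence.
* Listwise deletion can discard up to ~20% of respondents at the default
  missingness rates; no imputation is offered.
* `inject_dependence()` re-samples node columns jointly, so raw answer
  items are no longer coherent with re-sampled scores; it is a tool for
  estimator validation, not for constructing fully consistent synthetic
  records.
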