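# exponet

Exposome scores and mixed graphical model networks for psychopathology.

Psychiatric epidemiology increasingly summarizes cumulative environmental
risk as a single **exposome score (ES)** and asks how it relates to
*multiple* symptom domains at once rather than to a single diagnosis.
`exponet` is a reusable R implementation of that analysis for researchers
working with cross-sectional survey data: it scores the ES from raw
self-report answers, estimates a regularized partial-association network
over the ES, six symptom sum-scores (PHQ-9, GAD-7, MDQ, ASRS-5, OCI-R,
PQ-16) and covariates, and quantifies how stable the resulting network is.
Because participant-level data of this kind are usually private, the
package also ships a calibrated synthetic-cohort generator and a Gibbs
sampler for known mixed graphical models, so the whole pipeline is
testable end to end.

## The model

**Exposome score.** Ten binarized exposures (winter birth, obstetric
complications, advanced paternal age, non-right-handedness, emotional
neglect, emotional abuse, bullying, sexual abuse, problematic cannabis
use, urban upbringing), each weighted by the log odds ratio from
meta-analyses:

    ES_i = (1/K) * sum_k x_ik * ln(OR_k)

with `K = 10` by default (a per-respondent-recorded denominator is
available).

**Network.** A pairwise mixed graphical model: nodewise L1-penalized
regression (linear for continuous nodes, logistic for binary nodes) solved
by coordinate descent, per-node penalty chosen by the extended BIC
(gamma = 0.25), edges aggregated with the conservative AND rule as the
mean absolute standardized coefficient. Node **strength** is the sum of
incident absolute edge weights; **predictability** is the variance
explained (continuous) or normalized classification accuracy (binary) by
a node's selected neighbors.

**Stability.** Non-parametric and case-drop bootstraps with the
correlation-stability coefficient (CS-C; the largest case-drop proportion
at which 95% of iterations correlate at least 0.7 with the full sample;
values above 0.25 are conventionally acceptable), plus bootstrapped
difference tests for edges and strengths.

## Worked example

```r
library(exponet)

# a synthetic cohort calibrated to published sample marginals
co <- generate_cohort(cohort_spec(n_respondents = 2000, seed = 1))
es <- score_cohort(co)
round(c(mean_es = mean(es$score), sd_es = sd(es$score)), 3)
#> mean_es   sd_es
#>   0.246   0.108

# the packaged example network (11 nodes: ES, six symptom domains,
# age, education, gender, employment)
net <- example_network()
network_summary(net)
#> Network summary: 22 of 55 possible edges non-zero ( 40.0% )
#>   strength:
#>     D          0.904
#>     OCD        0.864
#>     PLEs       0.863
#>     ADHD       0.829
#>     ANX        0.826
#>     Ed         0.806
#>     Emp        0.800
#>     G          0.666
#>     M          0.544
#>     ES         0.481
#>     Age        0.421
```

The mean synthetic ES (0.246) matches the analytic expectation
`sum(prevalence * weight) / 10 ~ 0.245` for the default prevalences. In
the example network, 22 of 55 possible edges are non-zero (40.0%),
depressive symptoms (D) carry the highest strength centrality (0.904) and
the exposome score one of the lowest (0.481) — the ES connects directly
to psychotic-like experiences, manic and ADHD symptoms with small,
mutually similar weights.

The full pipeline (simulate → score → estimate → bootstrap → report)
runs from one call or a YAML config:

```r
run_pipeline(list(cohort = list(n = 1100, seed = 1),
                  bootstrap = list(enabled = TRUE, B = 1000),
                  output_dir = "run1", seed = 1))
```

writing the cohort, per-respondent scores, edge list/matrix,
predictability, centrality and stability reports, a GraphML export, and a
manifest that makes re-runs byte-identical. A thin command-line wrapper is
installed at `inst/scripts/run_pipeline.R`.

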