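# akireason

Individual predictive-reasoning analysis of acute kidney injury (AKI)
during immune-checkpoint-inhibitor (ICI) therapy.

## What this package does, and for whom

AKI complicates 14-18% of ICI-treated cancer courses, and its causes —
hypovolemia, drug injury (including immune-related adverse events),
infection, cancer cachexia — are individually heterogeneous but collapse
into the same creatinine rise. For clinical ML researchers and
pharmacoepidemiologists, `akireason` provides a tested pipeline that:

1. detects and stages creatinine-defined AKI under KDIGO criteria
   (SCr rise ≥ 0.3 mg/dL within 48 h or ≥ 1.5× baseline within 7 days;
   stages 1–3 by the 7-day peak);
2. continuously predicts AKI within 7 days with a gradient-boosted
   decision-tree model over sliding 4-week windows of EHR features
   (patient-level 80/20 split, 5-fold CV tuning, decision threshold set
   at precision 0.25 on out-of-fold predictions);
3. computes exact TreeSHAP attributions φ per frame on the margin scale,
   satisfying local accuracy `f(x) = φ₀ + Σᵢ φᵢ(x)`;
4. clusters each AKI patient's *predictive-reasoning signature* — the
   attribution vector of the top-K features at the last above-threshold
   prediction before first onset — by Ward hierarchical clustering, with
   a raw-feature-value comparator;
5. validates clusters against mechanism labels (Fisher exact /
   Kruskal–Wallis / χ² goodness of fit, adjusted Rand index) and 90-day
   post-AKI Kaplan–Meier survival with the log-rank test.

Because hospital EHR cohorts of this kind are not publicly deposited, the
package includes a synthetic EMR generator (`generate_cohort()`) with
planted, recoverable AKI mechanisms and mechanism-dependent survival; the
whole analysis runs end-to-end against it.

## Worked example

```r
library(akireason)
res <- run_aki_pipeline(cohort_config(n_patients = 600, seed = 7))
```

The numbered scripts under `analysis/` run the same pipeline stage by
stage and narrate what they find. With the shipped defaults they print:

```
AKI: 84 of 562 analyzable patients (14.9%); stages: 1=39, 2=35, 3=10
held-out test AUROC: 0.997 on 7678 frames (112 patients)
precision at threshold on out-of-fold pool: 0.250 (1160 flagged)
modal mechanism label per cluster:
  cluster     modal_label  n
1       1       Infection 15
2       2     Hypovolemia 25
3       3    Drug-related 19
4       4 Cancer Cachexia 13
mechanism recovery ARI: SHAP 0.805 vs raw 0.545
90-day log-rank across clusters: chisq 9.97, p = 0.01885
```

Reading: ~15% of analyzable synthetic patients develop KDIGO AKI; the
classifier separates positive from negative frames almost perfectly on
held-out patients (the planted signatures are cleaner than real EHR
data); each of the four attribution-signature clusters is dominated by a
distinct planted mechanism, and the clusters recover the mechanisms far
better than clustering the same patients on raw feature values
(ARI 0.81 vs 0.55); cluster survival separates at p < 0.05, with the
cancer-cachexia cluster worst — mirroring the qualitative findings the
analysis is designed to reproduce.

## Layout

```
R/                  package code: generator, KDIGO detection, features,
                    predictor, attributions, clustering, validation
analysis/01..08_*.R stage-by-stage narrative drivers (write to results/)
scripts/acceptance.R end-to-end metric recomputation
tests/testthat/     oracle-backed unit, property and acceptance tests
vignettes/          methods vignette (model, assumptions, design choices)
```
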