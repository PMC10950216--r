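---
title: "Methods: individual predictive reasoning for AKI during checkpoint-inhibitor therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual predictive reasoning for AKI during checkpoint-inhibitor therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acute kidney injury (AKI) is a frequent, prognostically serious
complication in cancer patients treated with immune checkpoint inhibitors
(ICIs), with reported incidences of 14-18%. Its causes are heterogeneous —
volume depletion, nephrotoxic or immune-mediated drug injury, infection,
and the terminal wasting of cancer cachexia all produce the same
creatinine rise — and standard cohort-level risk models say nothing about
*why a particular patient* is predicted to be at risk at a particular
moment.

`akireason` implements an individual-level analysis of that question: a
gradient-boosted decision-tree (GBDT) model continuously predicts AKI
within 7 days from sliding windows of routine EHR data; exact Shapley
attributions decompose every prediction into signed per-feature
contributions; each AKI patient's attribution vector immediately before
their first episode — their *predictive-reasoning signature* — is
clustered hierarchically; and the clusters are validated against
mechanism labels and 90-day post-AKI survival. Hospital EHR data of this
kind are not publicly deposited, so the package ships a synthetic cohort
generator that emulates the relevant statistical structure with planted,
recoverable ground truth.

## The synthetic cohort generator

`generate_cohort(cohort_config())` simulates, per patient: a registry row
(age band, sex, cancer type, ICI agent, ICI start date), timestamped labs
(serum creatinine, BUN, CRP, LDH, albumin, WBC, eosinophils), medication
exposures (PPI, NSAID, diuretic, ICI cycles), dietary-intake and
body-temperature observations, and inpatient intervals.

Key design choices, fixed once as the study conditions:

* **AKI mechanisms are assigned before any trajectory is simulated**
  (18% of patients by default), so nothing downstream can leak into the
  assignment. Each mechanism drives a creatinine ramp reaching 1.6-3.5x
  baseline over 3-10 days (severity mixture aimed at a mostly-stage-1
  cohort) and imprints a 4-week feature signature: hypovolemia (diuretics,
  falling intake, rising BUN/SCr), drug-related (PPI/NSAID, low-grade
  fever, eosinophilia as an immune-related adverse-event marker), cancer
  cachexia (monotone CRP/LDH rise, falling albumin, poor intake,
  hospitalization), infection (abrupt CRP/WBC spike, high fever).
* **Baseline creatinine** is lognormal with median 0.8 mg/dL (matching the
  0.79 [0.66-0.95] IQR typical of such cohorts); day-to-day physiology is
  AR(1) on the log scale; assay noise is proportional to the level
  (`noise_sd_scr` is the SD at the median baseline).
* **Between-patient heterogeneity**: companion-lab baselines carry large
  patient-level random effects (CRP lognormal with sdlog 1.0, etc.), each
  planted signature is scaled by a per-patient severity in [0.5, 1], and
  25% of AKI patients receive a mild comorbid secondary signature. Real
  oncology labs behave this way, and it is precisely this nuisance
  variation that makes *raw-value* clustering a poor mechanism readout
  while attribution signatures remain informative. With these effects
  removed the generator would be too clean: raw values would encode the
  mechanism directly, which no real EHR does.
* **Sampling**: outpatient lab gaps are geometric (mean
  `lab_cadence_days` = 5 days) with daily-to-2-day sampling while
  inpatient, mirroring the inpatient/outpatient data-availability
  asymmetry of hospital records.
* **Survival**: post-AKI death is exponential with a mechanism-specific
  daily hazard (defaults 0.002-0.005/day, cancer cachexia 0.015/day, i.e.
  the poorest prognosis), acting once the creatinine ramp is established;
  a small background hazard (4e-4/day) applies throughout.

What the generator does **not** emulate: coded diagnoses, free text,
imaging, urine output, multi-mechanism ground truth (each patient has one
primary mechanism label), and realistic pharmacokinetics. Passing tests
therefore demonstrate that the pipeline recovers planted structure of the
stated form — not that it would achieve the same numbers on real hospital
data, where signatures are weaker and annotation is noisier.

## KDIGO episode detection

AKI is creatinine-defined: an episode opens at the first measurement
`t >=` ICI start where SCr exceeds some measurement from the previous 48
hours by >= 0.3 mg/dL, or reaches 1.5x some measurement from the previous
7 days (the full KDIGO windows; a window-free variant against the running
baseline is selectable because one-line definitions in the clinical
literature often omit the windows). The baseline is the minimum over the
7 days before the reference date, falling back to the most recent value
within 90 days. Staging uses the peak within 7 days of onset: stage 1 =
1.5-1.9x baseline (or +0.3 mg/dL), stage 2 = 2.0-2.9x, stage 3 = >= 3.0x
or peak >= 4.0 mg/dL (no urine-output or RRT criteria; creatinine only).
A subsequent episode can open only after the 7-day staging window closes —
this convention makes "episode" well-defined and is applied identically in
the brute-force oracle used by the tests. Patients with a second episode
within 14 days of the first are flagged and omitted from the clustered
evaluation set (their frames still contribute training labels). Cohort
filters remove ESRD at baseline, patients with no creatinine after ICI
start, and patients censored *alive* before 90 days; death before 90 days
is an outcome, not censoring — excluding those patients would empty the
poorest-prognosis cluster.

Ratio comparisons carry a 1e-9 tolerance so that printed two-decimal
creatinine values land on the intended side of stage boundaries
(2.4/0.8 is exactly 3.0, not 2.9999...).

## Features and labels

One prediction frame per (patient, lab date). Four weekly look-back
windows `(-1wk)` ... `(-4wk)` tile the 28 days up to and including the
reference date, half-open on the early side; labs aggregate as `last` and
`max` per window (plus BUN/SCr ratio of window-lasts), medications and
inpatient status as window `any`, observations as window `mean`, and
registry fields enter as static codes — about 100 features from ~40 raw
variables. The label is positive iff an episode onset falls in
`(reference, reference + 7 days]`. Absent lab values stay missing and are
passed natively to the learner (GBDT handles missingness without
imputation); absent medications are 0. Anti-leakage is tested by
mutation: perturbing any data after the reference date leaves the frame
unchanged.

## Model, tuning, and the decision threshold

The classifier is xgboost's histogram GBDT (single-threaded for exact
reproducibility), with the positive class up-weighted by the
negative/positive frame ratio rather than resampling, preserving the
probability calibration the threshold rule needs. Patients (never frames)
are split 80/20, stratified on AKI status; a declared 8-point grid over
tree depth (3/5), learning rate (0.1/0.3) and minimum child weight (1/5)
at 120 rounds is scored by 5-fold patient-level cross-validated AUROC;
the winner is refit on all training frames. The decision threshold is the
smallest probability cut whose precision on the pooled out-of-fold
predictions reaches 0.25 (ties resolved toward the lower cut, i.e. higher
recall); the held-out test set is touched exactly once, for the final
AUROC.

## Attributions

`compute_attributions()` returns exact TreeSHAP values on the margin
(log-odds) scale, where additivity is exact: per frame, base value plus
the sum of attributions reproduces the model margin. The learner stores
contributions in float32, so the identity is asserted at 1e-6 *relative
to the summation scale* (|base| + sum|phi|) — the correct conditioning
denominator for a sum of ~110 float32 terms. The test suite also checks
TreeSHAP against a power-set Shapley enumeration with the cover-weighted
(path-dependent) conditional expectation on small enumerable ensembles.
The attribution background is the training population as encoded in the
trees' cover statistics; a probability-scale view is not offered because
additivity is only approximate there.

## Reasoning signatures and clustering

The signature frame is the latest prediction point strictly before first
onset with probability >= the decision threshold; if none exists the
latest pre-onset point is used and the patient is flagged `subthreshold`
but retained, keeping the clustered set equal to the AKI cohort. The
signature vector holds the attributions of the K = 20 globally
top-ranked features (by mean |SHAP| over all frames) at that single frame
— "immediately before" the episode, not a window average (a window-mean
variant exists behind a flag).

Clustering is agglomerative with Euclidean distance and Ward linkage
(both arguments exposed), rows pre-sorted by patient id so results are
input-order invariant, with the full tree retained for re-cutting. One
deliberate choice deserves emphasis: **signature vectors are
z-standardized per feature before clustering**. Although attributions
share the margin scale, their variances differ by orders of magnitude
across features, and unscaled Euclidean distances turn out to be governed
by the one or two highest-variance columns and by overall prediction
confidence — clustering patients by *severity* rather than by the
*pattern* of reasoning. Standardizing restores pattern clustering and
makes the comparison with the raw-value comparator like-for-like, since
the comparator (`cluster_raw_values()`: identical algorithm on the same
patients, same features, same frames) must z-score its inputs anyway to
mix units. Zero-variance features are dropped with a warning; an
all-constant matrix is flagged degenerate rather than erroring. The
number of clusters defaults to a fixed k = 4 (the dendrogram-inspection
analogue); a mean-silhouette search over k in [2, 8] is available.

## Validation

* **Characteristics table**: per-cluster sex, age band, cancer type,
  first-episode stage, inpatient status at onset (Fisher's exact test;
  seeded Monte-Carlo with 1e5 draws beyond 2x2) and baseline creatinine
  (Kruskal-Wallis). Per-row p < 0.05 without multiplicity correction, as
  is conventional for such tables; a Holm-adjusted column is emitted
  alongside for transparency.
* **Label distribution**: per-cluster counts of the six mechanism labels
  with a chi-square goodness-of-fit test against the pooled marginal;
  expected counts below 1 collapse into "Others".
* **Survival**: Kaplan-Meier from first onset, capped at 90 days
  (censored at the cap when alive); patients with no post-onset follow-up
  contribute time 0 censored and are flagged. The k-group log-rank test
  comes from `survival::survdiff`; tests verify it reduces to the
  hand-computed two-sample statistic and that the product-limit curve
  matches a brute-force oracle.
* **Recovery score**: adjusted Rand index from the pair-counting closed
  form, computed over clustered patients carrying a planted mechanism
  (noise-driven AKI patients, labelled "Others", are excluded from the
  score; they have no mechanism to recover).

## Problem sizes and reproducibility

The analysis scripts and the acceptance script use a 600-patient cohort
for the main run, ten 350-patient replicates for the paired SHAP-vs-raw
comparison, and twenty 220-patient replicates for the log-rank power
experiment — sizes at which every planted effect is comfortably
detectable and a full run completes in minutes on one core. All
randomness flows from explicit integer seeds through a splitmix-style
sub-seed scheme, and training is single-threaded, so identical configs
reproduce identical results to machine precision.

## Known limitations

Single-frame signatures ignore the temporal evolution of attributions
(the heatmaps exported by `heatmap_export()` show it, but clustering does
not use it); mechanism ground truth is single-valued; the generator's
signatures, though noised, remain cleaner than real chart-review
annotation, so recovery metrics here are upper bounds on what real data
would give; and the creatinine-only KDIGO implementation misses
urine-output-defined AKI entirely.
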