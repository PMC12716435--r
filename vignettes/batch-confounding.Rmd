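---
title: "Auditing batch confounding in ovarian cancer screening classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing batch confounding in ovarian cancer screening classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovascreen)
```

## The problem

Blood-based ovarian cancer screening classifiers combine the serum proteins
CA125 and HE4, sometimes with cell-free DNA (cfDNA) features such as
chromosome-arm copy-number Z scores. When a subset of the training samples is
processed in its own sequencing library batches, and those batches contain
only cases (no healthy donors, no validation samples), any technical offset
that the batches impose on the genomic features becomes statistically
indistinguishable from a cancer signal. Cross-validation then rewards the
model for learning the batch, not the biology, and the apparent performance
does not transfer to independent data.

`ovascreen` implements the full audit workflow for this failure mode:
reference-interval (zlog) preprocessing of the protein concentrations, the
balanced L2-penalised logistic-regression modelling protocol with repeated
stratified cross-validation, single-feature AUC screens that quantify how
strongly each feature predicts the processing era rather than the disease,
a restricted retraining that removes the suspect samples, feature-importance
accounting, and the clinical operating-point arithmetic (threshold at a
specificity floor, sensitivity, PPV at population prevalence). A synthetic
cohort generator reproduces the confounded structure so that every stage is
testable without access to the original data.

## The model

For features $x$ and labels $y \in \{0, 1\}$ (1 = cancer), `plr()` minimises

$$\tfrac12 \lVert w \rVert_2^2 \;+\; C \sum_i \omega_i
  \log\bigl(1 + e^{-\tilde y_i (w \cdot x_i + b)}\bigr),
  \qquad \tilde y_i = 2y_i - 1,$$

with the intercept $b$ unpenalised and balanced class weights
$\omega_i = n / (2\,n_{\mathrm{class}(i)})$, so each class contributes half
of the total loss weight regardless of imbalance. `C = 1` weighs the ridge
penalty equally with the error term. The problem is strictly convex; a
damped Newton iteration drives the gradient below $10^{-8}$ (or to the float
precision limit with gradient below $10^{-6}$ on quasi-separated fits), so
refitting from any initialisation reproduces the coefficients to well under
$10^{-6}$ — the fit is effectively deterministic across platforms.

The cross-validation protocol is 5-fold stratified, repeated 10 times;
each sample's score is the mean of its 10 held-out predictions. Fold
partitions for repeat $r$ derive from `seed + r`, so repeats differ but the
run is reproducible. The positive-class score is the predicted probability
of cancer.

### zlog preprocessing

Protein concentrations are mapped to an approximately standard-normal scale
through the reference interval $[L, U]$ of a healthy population (treated as
2.5th/97.5th percentiles):

$$z = \frac{\ln x - (\ln L + \ln U)/2}{(\ln U - \ln L)/3.92},$$

so $z(L) = -1.96$, $z(U) = +1.96$. Defaults: $U = 35$ U/mL for CA125 and
$U = 140$ pmol/L for HE4; where no lower limit is established, the
conventional heuristic $L = 0.15\,U$ applies (5.25 and 21). Natural
logarithms are used throughout, and `inverse_zlog()` inverts the map exactly.
Protein zlog features enter the models without further standardisation
(they are already on a reference scale); a `standardize` flag exists for
multi-feature models but defaults off, with training-set SDs retained on the
fitted object for the importance calculations.

## The audit

* `prefix_confounding_screen()` restricts to the discovery-cohort cancer
  samples and computes, per feature, the orientation-free rank AUC
  ($\max(a, 1-a)$, midranks for ties) for predicting the sample-ID prefix.
  A feature above 0.75 separates processing eras, not biology. The
  orientation-free rule makes 0.5 the minimum reportable value; the flag
  uses a strict inequality.
* `condition_auc_screen()` computes the same statistic for cancer
  prediction (screening: vs healthy; diagnostic: vs benign), optionally
  within one prefix to keep the evaluation clear of the confounded subset.
* `anova_order()` ranks features by a classical equal-variance one-way
  ANOVA across prefixes within the cancer samples; with two groups
  $F = t^2$ of the pooled t-test. `standardize_features()` (sample SD,
  $n-1$; a population-SD option is provided) prepares the matrix for
  heatmap display in that order.
* `batch_composition()` flags batches that mix discovery and validation
  samples (data leakage through shared processing) and batches holding a
  single condition (case status inseparable from the batch).

## Clinical operating points

`threshold_at_specificity()` selects the minimal score threshold achieving a
specificity floor (default 99%): a sample is called positive when its score
strictly exceeds $t$, and $t$ is the $\lceil \mathrm{floor}\cdot n\rceil$-th
order statistic of the negative scores, so with 182 negatives the achieved
specificity is $181/182 = 99.5\%$. The strict-inequality convention is what
makes the order-statistic rule give specificity exactly $k/n$. The
alternative `"zero_fp"` rule (threshold above the highest negative score,
100% in-sample specificity) is provided for comparison: a single extreme
healthy outlier drags it arbitrarily, whereas the minimal-floor rule moves
by at most one order statistic.

PPV follows $\mathrm{se}\cdot p / (\mathrm{se}\cdot p +
(1-\mathrm{sp})(1-p))$ with a default prevalence $p = 0.145\%$ (the 2022
U.S. ovarian-cancer figure), overridable. For a single-marker model,
`threshold_to_concentration()` maps a score threshold back through
$z = (\mathrm{logit}(t) - b)/w$ and the inverse zlog transform to a
concentration in the marker's units.

Feature importances follow the stated convention exactly: a scaled
coefficient is the raw coefficient *divided* by the feature's training-set
SD, and a feature's importance is its absolute scaled coefficient over the
sum of absolute scaled coefficients. The conventional standardised
coefficient (multiplying by the SD) is exposed as an explicitly labelled
`mode = "multiply"`; the two modes rank features differently and are never
mixed within a comparison.

## The synthetic world

`default_cohort_spec()` encodes the audited study's printed structure: 479
samples, of which 85 carry the affected prefix ("PGDX") and sit exclusively
in discovery batches 1–16 with no healthy and no validation samples
(42 cancer, 43 benign), while the 394 unaffected ("CGPL") samples fill
batches 17–38. Discovery holds 182 healthy and 94 cancer samples (42
affected + 52 unaffected). No validation-cohort condition
counts are published, so the defaults — 60 healthy, 30 benign, 30 cancer, plus 40
unaffected discovery benign — are documented choices that preserve the
published totals. By default discovery and validation share the unaffected
batches (the leakage the audit flags); `leakage_mode = FALSE` splits the
batch range instead. Affected batches are single-condition unless
`mix_batch10 = TRUE`, which reproduces the one mixed cancer/benign batch.

Distributional choices (no forms are published):

* **Proteins** are bivariate log-normal, expressed on the zlog scale:
  healthy samples are standard normal there, condition shifts are additive
  in log concentration in units of the healthy log-SD, and the two log
  concentrations correlate at 0.57 (the observed discovery-cohort
  correlation of the zlog values; attainment is approximate, not asserted).
  Cancer log-scale is 1.5× healthy, reflecting the order-of-magnitude wider
  pathological range. The default shifts are fixed by inverting the
  binormal AUC formula against the published single-feature AUCs —
  screening AUCs above 0.9 for both proteins, diagnostic AUCs of 0.90 (HE4)
  and 0.79 (CA125) — giving cancer shifts of 3.0 (CA125) and 2.6 (HE4) and
  benign shifts of 1.5 and 0.3. The benign values place benign CA125 closer
  to cancer than benign HE4, which is what makes HE4 the stronger
  diagnostic marker, as observed.
* **Copy-number features** (39, named by chromosome arm) are standard
  normal, with a weak additive cancer effect (+0.3 SD on 8 arms: real but
  individually below the 0.75 importance threshold, matching the
  observation that no copy-number feature cleared 0.75 within the
  unaffected samples) and an additive batch offset (−2 SD by default, −3 SD
  in the recovery experiments) on 17 of 39 arms for samples in affected
  batches. The identity of the 17 arms is illustrative — the study names
  only 11p, 18p and 19q as the strongest — and is configurable.
* All randomness flows from one seed; identical `(spec, seed)` pairs
  reproduce output bit-for-bit.

### What a green test does and does not establish

The generator reproduces the *statistical geometry* of the confounding —
counts, batch composition, effect directions and magnitudes on the stated
scales — not the data themselves. Copy-number features are generated
independently across arms, whereas real arm-level Z scores are strongly
correlated through shared coverage; protein assay error beyond log-normal
spread is not modelled; and fragmentation features default to zero columns.
Green confounding-recovery tests therefore establish that the *pipeline*
detects and removes the designed confounding, not that the published AUCs
are reproduced: those require the original archived cohort. The published
headline AUCs (cross-validation 0.96 vs validation 0.93 confounded; 0.94 vs
0.95 restricted) are reproduced directionally, not numerically.

### A limitation found by the tests

One published phenomenon does **not** transfer to this synthetic world: the
drop in total copy-number importance share after restriction. In the
original study the restricted model was built with the original authors'
sparse architecture, in which most copy-number coefficients are exactly
zero. Under the L2 objective at `C = 1`, nothing is ever exactly zero:
restriction removes 42 of 94 cancer samples, and the smaller, more heavily
reweighted training set *inflates* the overfit coefficients spread across
the 39 independent copy-number noise features; meanwhile the batch offset
inflates the affected features' training SD, which deflates their
divide-by-SD importance in the confounded model. The two effects roughly
cancel, and the importance share moves the expected way in only about half
of the simulated cohorts. The package reports this honestly (the
corresponding acceptance test is expected to fail) and the per-feature
comparison (`compare_importances()`) remains the reliable instrument: the
batch-affected features themselves always lose their weight after
restriction. This is also a practical reminder of the study's own point
that with fewer than ~300 training samples the feature count must be kept
low to avoid overfitting.

## Worked example

```{r example, eval = FALSE}
cfg <- run_config(spec = default_cohort_spec(), context = "screening",
                  seed = 1)
res <- run_full_analysis(cfg, "audit_report")
res$summary[c("cv_auc", "validation_auc",
              "restricted_cv_auc", "restricted_validation_auc")]
print(res$thresholds$full)
print(res$audit)
```

The report directory contains every artifact as plain text (TSV/JSON/YAML),
with the seed and configuration echoed; rerunning with the same
configuration reproduces each file bit-for-bit.

## Numerical choices

* Optimizer: gradient tolerance $10^{-8}$; quasi-separated fits stop at the
  float-precision limit with gradient below $10^{-6}$.
* AUC ties: midranks (the standard Mann–Whitney estimator, matching the
  brute-force pairwise oracle used in the tests); exact score ties in
  threshold scans resolve through the order-statistic rule, never inside an
  AUC.
* Importance flag: strict `> 0.75`.
* Condition/cohort labels: normalised case-insensitively with a small
  documented synonym map (`no known lesions` → healthy, `malignant` →
  cancer, `training` → discovery, `test` → validation); anything else is an
  error.
* Degenerate inputs error early and name the offending feature or sample:
  constant features in standardisation, single-class AUC inputs, exclusions
  that empty a class.
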