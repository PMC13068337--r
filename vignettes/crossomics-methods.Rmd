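---
title: "Benchmarking cross-omics prediction in paired microbiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking cross-omics prediction in paired microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Paired microbiome cohorts measure several molecular layers on the same stool
samples: gene-family content from shotgun metagenomics (mGx), transcripts
(mTx), proteins (mPx) and metabolites (mBx). Measuring every layer is
expensive, so a natural question is how much of one layer can be predicted
from another, which features are reliably predictable, and whether predicted
layers remain useful for downstream tasks such as disease classification.
`crossomics` implements a benchmark pipeline for these questions:
preprocessing of compositional abundance tables, a family of multi-output
regressors, patient-level resampling evaluation with rank-correlation
scoring, robustness analyses of the well-predicted feature core, and a
fairness-controlled inflammatory bowel disease (IBD) classification task.
Because real cohorts are large downloads with restrictive licenses, the
package also ships a synthetic cohort generator with planted ground truth,
which turns the whole pipeline into a testable parameter-recovery problem.

## Preprocessing model

Abundance tables are samples × features with relative abundances (rows
closed to 1 by total-sum scaling) or raw counts. The pipeline follows the
standard compositional treatment:

* **Zero imputation.** Relative tables receive ε = 1e-7 on every entry
  (below any observed nonzero value), count tables a pseudocount of 1.
  After ε-imputation, rows are re-closed to sum 1 so that the centered
  log-ratio still operates on a composition; whether to re-close is not
  canonical, so it is an explicit argument (`renormalize`).
* **Filtering.** Two prevalence/abundance filters for sparse features.
  Lenient: keep a feature iff it reaches 0.005% abundance in more than 10%
  of samples and has at most 95% zeros. Strict: the abundance threshold
  rises to 0.01% and features below 0.0001% in more than 10% of samples are
  additionally removed. "More than 10%" is a strict inequality, so a
  feature at exactly 10% prevalence fails; lenient retains a superset of
  strict by construction. With the `>10%` prevalence rule the 95%-zeros rule
  is never the binding constraint, but it is retained (and reported as the
  dropping reason when it applies) because it is part of the declared
  procedure.
* **De-stratification.** Functional profilers report enzyme (EC) features
  both in total and per contributing taxon (`EC|taxon`); summing the
  stratified columns per EC conserves each sample's mass while reducing
  dimensionality and sparsity. The delimiter defaults to `|` and is
  configurable.
* **Pairing.** Input and output tables are restricted to their shared
  samples in a stable order; multi-omics inputs are column-concatenated
  with modality-prefixed feature ids.

Filtering can be applied globally (the default, matching how public cohort
tables are usually prepared) or inside each training partition to avoid any
selection leakage; both modes use the same code path.

## Transforms

Three per-feature representations feed the regressors, all fitted on
training samples only:

* **CLR** (centered log-ratio): `clr(x)_i = log(x_i / g(x))` with `g` the
  row geometric mean. Requires strictly positive entries; rows map to
  vectors summing to 0. Scale-invariant with respect to pre-closure
  multiplication of a sample.
* **Arcsin square root**: `asin(sqrt(x_i))`, defined on [0, 1] without
  imputation; zeros map to 0.
* **Quantile-normal**: per feature, the empirical CDF of the training
  values, with (rank − 0.5)/n plotting positions, composed with the
  standard normal quantile function. Unseen values are clamped to the
  training range and interpolated linearly between training quantiles;
  extreme quantiles are clipped to (1/2n, 1 − 1/2n) so outputs stay finite.
  Constant training features map to zero with a warning. The convention is
  pinned here because library defaults differ and bit-stability matters
  for reproducible runs.

Evaluation is rank-based (Spearman), so for any strictly monotone
per-feature transform the choice of evaluation space is immaterial.
Predictions are therefore scored in the model's native output-transform
space against the identically transformed held-out truth, and no inverse
transform is applied.

## Partitioning

Longitudinal cohorts repeat samples within patients; splitting at the
sample level would leak patient identity. Plans operate on patients:
patients are grouped by diagnosis (UC, CD, HC), shuffled under the plan's
seed, and 20% of each class (ceiling, so no class has an empty test side)
is assigned to the test set. Ten plans under seeds 0–9 are the default;
the seed list is configurable. Patients whose samples carry conflicting
diagnoses are rejected at load. Inner cross-validation (for classifier
tuning) partitions the training patients into 5 stratified folds.

## Regressors

* **Elastic net** (the reference model): one linear model per output
  feature via coordinate descent (`glmnet`), mixing parameter fixed at 0.5,
  penalty chosen per feature by internal cross-validation over a 13-point
  log-spaced grid `10^[-4, 1]`, with CV folds grouped by patient.
  Constant transformed outputs get a constant predictor and a flag.
* **Random forest baseline**: one forest per output feature (`ranger`,
  100 trees, shared seed 42). A single multivariate-response forest would
  match the module's description more literally, but no multivariate
  implementation is available, and per-output forests expose the same
  interface and scoring.
* **Feed-forward network**: two hidden layers (512/256, ReLU, dropout
  0.1), full-batch Adam on MSE, 1000 epochs at learning rate 5e-3.
  Fixed-epoch training is the default: when many output features are
  unlearnable noise, early stopping on the total validation loss halts
  before the learnable outputs are fit; early stopping on a patient-level
  validation slice remains available (`validation_fraction`). Optional
  augmentation expands the training set to `n`× its size with Gaussian
  jitter in transformed input space (per-feature SD = 0.1× the training
  SD); an augmentation factor of 1 means no augmentation.
* **Autoencoder + elastic net**: a linear encoder to a latent space
  (default 32) trained with joint loss `MSE(reconstruction) +
  λ·MSE(regression)`, then the elastic net fitted on the frozen latent
  features. Intended for concatenated multi-omics input.
* **Feature-selection pre-training**: 10 patient-level folds inside the
  training partition, a forest per fold, per-feature Spearman on each
  fold's held-out part, averaged; the top fraction (1.0/0.5/0.25/0.10) of
  output features by mean score is retained, ties broken by feature id.

Default transform pairings: CLR/CLR for the linear families and the
forest, quantile/quantile for the network; every pairing can be
overridden per fit.

## Evaluation

Per output feature, predictions on held-out samples are compared with the
truth by Spearman's rank correlation (Pearson on average ranks; an
undefined correlation from a constant vector is recorded as 0 with a
flag — common for very sparse layers, and documented rather than hidden).
Across the 10 partitions the per-feature mean and SD are formed; the
reported score is the mean over the top-k features (k = 50 on real-scale
data; k must not exceed the feature count) and the reported error is the
mean per-feature SD over those features. Ties at the top-k boundary are
resolved by feature id so reported numbers are deterministic.

Robustness analyses: pairwise Jaccard similarity of top-25% sets across
partitions or input types, with the all-way intersection as the "core"
set; feature variance (on test-set truth values) versus prediction
quality, tested by Spearman association; enzyme-class enrichment of the
top sets by Fisher's exact test on the first EC digit, reported as the
sample odds ratio `(a/b)/(c/d)` with the exact two-sided p-value; and
between-model comparisons by two-sided Mann–Whitney tests on per-feature
mean correlations (exact below 50 per sample without ties, normal
approximation with tie correction otherwise; completely tied inputs
return p = 1 by convention).

## Downstream classification

UC and CD collapse to IBD for a binary task against HC. For each split
and each data source (input layer, predicted layer, ground-truth layer),
the training set is downsampled to the size of the smallest source and
then to exactly equal class counts, so every source trains on the same
amount of data; test sets are the shared held-out samples (test sets are
not balanced — only training balancing is part of the protocol, and
balanced accuracy handles test imbalance). The classifier is a random
forest tuned by 50 iterations of random search (trees 100–1000, depth
unlimited/4–32, min node size 1–8, mtry sqrt/log2/0.3) maximizing
balanced accuracy over 5 patient-level stratified folds, then refitted on
the balanced training set. Metrics: balanced accuracy (headline), ROC-AUC
(rank-based; undefined and flagged on single-class test sets), precision,
recall and F1 for the IBD class. A stratified dummy classifier (sampling
labels from the training distribution; expected balanced accuracy 0.5)
anchors every comparison, and classifiers are compared across the 10
splits by Mann–Whitney tests.

## The synthetic cohort generator

No generative description of the real data exists, so the generator's
distributional choices are explicit stand-ins that reproduce the features
the analysis depends on — compositional closure, heavy zero-inflation,
high dimensionality relative to sample count, longitudinal nesting, a
sparse planted cross-omics dependency, and a planted disease signal:

* **Latents.** Input features are log-normal: `z = μ_feature +
  u_{patient,feature} + ε`, with a per-(patient, feature) random
  intercept (SD 0.5) creating the within-patient correlation that
  motivates patient-level splitting, and unit-SD sample noise. The latent
  scale is log-normal rather than Dirichlet so the planted map is exactly
  linear in CLR space, which makes elastic-net recovery a valid oracle
  for the whole pipeline.
* **Planted map.** Each of the 10 signal output features is a sparse
  linear combination (5 nonzero ±Uniform(0.5, 1.5) coefficients) of the
  log-scale input latents plus Gaussian noise scaled so that the
  signal-to-noise variance ratio equals `signal_strength` (default 5).
  Non-signal outputs are independent noise with the same patient
  structure.
* **Disease signal.** Each cohort assigns one diagnosis per patient
  (defaults HC 0.40 / CD 0.35 / UC 0.25, CD most common as in IBD
  cohorts); UC and CD samples receive an additive log-scale shift
  (default 1.0) on the class features. Class features are planted in both
  layers: 10 in the output layer (preferring non-signal outputs, where
  the shift is not masked by the much larger planted-signal variance) and
  10 in the input layer chosen inside the planted coefficient support, so
  that predictions — which are functions of the inputs only — inherit the
  disease signal.
* **Zeros.** Structural zeros are placed in exact per-feature counts
  (realized sparsity equals the target by construction) and the modality's
  total zero mass (default 30% for the gene-family layer, 10% for the
  denser metabolite-like layer) is spread over the features that carry no
  planted role. Signal-support inputs, signal outputs and class features
  stay dense: a dependency routed through a mostly-absent feature, or a
  class marker mostly zeroed out, is unidentifiable by any method and
  would not be the planted effect the tests probe. This mirrors real
  cohorts, where the reliably predicted core consists of prevalent
  features. Per-feature targets are recorded in the returned truth object.
* **Randomness.** One master seed derives four named substreams (labels,
  intensity, presence, noise), so a change in one component's draw count
  cannot silently shift another component's values.

What the generator does **not** emulate: read-level sequencing noise,
LC-MS acquisition artifacts, batch effects, or temporal dynamics beyond
the patient intercept. Passing tests therefore demonstrate correctness of
the pipeline's statistics and the recoverability of planted structure
under realistic sparsity and nesting — not performance on any real cohort.

## Problem sizes and numerical choices

The default recovery cohort is 40 patients × 5 visits = 200 samples, 100
input and 50 output features, chosen so that every end-to-end analysis
(10-split elastic-net benchmark, permutation null, core-set analysis,
feature-selection pre-training, network comparison, and the downstream
classification protocol) completes comfortably on a single CPU while
keeping the high-dimensional flavour of the real problem. Unit tests use
smaller cohorts (≈12–20 patients) built by the same generator.

Other pinned choices: ε-imputed tables are re-closed before CLR; the
quantile map uses (rank − 0.5)/n positions with linear interpolation and
clamping; undefined Spearman values become 0 with a flag; top-k and
top-fraction ties break lexicographically; 20% test rounding is ceiling
per class; the classifier's random-search grid is a declared default of
this package; Fisher p-values are exact; Mann–Whitney
switches from exact enumeration to the tie-corrected normal approximation
at 50 observations per sample.

## Known limitations

* The per-output elastic net ignores correlation between output features;
  the network shares hidden layers but its architecture is a declared
  default, not a published one.
* The generator's planted linearity favours linear models by design; the
  forest and network are included as baselines, not as tuned competitors.
* Global filtering slightly leaks test-sample prevalence
  into feature selection; the split-aware mode avoids this at the cost of
  differing feature sets per split.
* Classifier comparisons across 10 splits have limited power; exact
  Mann–Whitney p-values below ~1e-4 are unattainable at that sample size.
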