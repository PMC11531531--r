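---
title: "Methods: a fuzzy deep pipeline for histopathology tile classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a fuzzy deep pipeline for histopathology tile classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyhisto)
```

## The problem and the approach

`fuzzyhisto` classifies tile-scale histopathology images (H&E-stained tissue,
binary cancer / non-cancer labels) with a hybrid of deep feature learning and
interpretable fuzzy rules. The pipeline has five stages:

1. **Augmentation.** Each training image yields the original plus one scaled
   copy (factor 1.2), one vertically flipped copy, and three copies rotated by
   random angles in ±50°, so a set of `N` tiles becomes `6N` (with `5N` newly
   synthesized).
2. **Feature extraction.** Images are resized to a square input (224 px for
   the convolutional backbone), per-channel mean intensities are subtracted,
   and each image is mapped to a fixed-length real vector. The backbone is
   pluggable: the published ResNet-50 architecture (final convolutional map
   7×7×2048, i.e. 100,352 features at input 224) when a deep-learning runtime
   is available, or a deterministic grid-pooled intensity extractor
   (`backbone = "stub"`) that keeps every downstream stage runnable and
   testable with no heavyweight dependency.
3. **Feature selection.** Recursive feature elimination driven by entropy-split
   decision trees: per round, trees are fit on stratified folds, held-out fold
   accuracy is recorded, the impurity-decrease importances are averaged over
   folds, and the least important 10% of surviving features are dropped until
   the target count remains.
4. **Rule induction.** Features with more than 10% exact zeros are discarded,
   the survivors are ranked by absolute Pearson correlation with the 0/1 label
   (point-biserial), and the top 8 become the rule variables. Each variable is
   discretized by a fuzzy partition (default: 9 triangular membership
   functions, uniformly spaced, adjacent levels crossing at 0.5). The
   Wang–Mendel procedure then emits one primitive rule per training sample —
   antecedent = the maximal-membership level per variable, degree = the product
   of those memberships, consequent = the label — collapses duplicates, and
   resolves antecedent conflicts by keeping the higher-degree rule.
5. **Classification.** A trainable network combines a dense pathway over all
   selected features (dense → ReLU → dense → ReLU on standardized inputs) with
   a fuzzification layer that turns the raw values of the rule variables into
   per-rule firing strengths `α_i = Π_j μ_ij(x_j)`. The hidden activations and
   `α` feed a joint output layer (`β_k = Σ_i α_i w_ik` plus the dense
   contribution and a bias) followed by a softmax. Training is minibatch Adam
   (learning rate 0.001, batch 32, cross-entropy), with a stratified 80/20
   train/validation split.

Performance is reported as a confusion matrix and the usual ratios — accuracy,
precision, recall/sensitivity, specificity, and F1 (`2TP/(2TP+FP+FN)`) — per
class and macro-averaged, with zero-denominator ratios reported as `NA` rather
than silently coerced to 0.

## Interpretation choices in the network wiring

Strictly sequential readings of "dense → ReLU → fuzzify → dense → ReLU →
defuzzify" are incompatible with the fuzzification formula, which is defined on
feature values with fitted partitions, not on ReLU activations of arbitrary
sign and scale. We therefore run the fuzzification layer **in parallel** on the
raw rule-variable values and concatenate its activations with the dense
pathway's hidden output at the defuzzification/output layer. This preserves
both the layer order of the dense pathway and the defining equations of the
fuzzy layers, and it is stated here prominently as an interpretation.

Two further choices in the same spirit:

* **Rule-to-class weights are trainable**, initialized from the rule
  consequents (one-hot times rule degree). Training them subsumes the fixed
  case; at initialization the rule pathway alone already votes sensibly.
* **The dense pathway's output weights start at zero**, so the epoch-0 model
  is exactly the fuzzy rule vote, and gradient descent grows the dense
  contribution from there. This makes short training runs well behaved and
  keeps the initial model interpretable.

## Leakage discipline

The train/validation split is drawn **before** rule induction, and the rule
base is built from the training rows only (`run_pipeline()` does this
internally; `fit_fuzzy_deep(split = ...)` exposes the same discipline to
callers). Wang–Mendel rules are sample-derived — one primitive rule per
sample — so inducing them on the full table would memorize validation labels
in the rule base and inflate validation accuracy. The package's label-shuffled
negative control (which must sit near 50%) only behaves correctly under this
protocol, and it is how we caught the issue.

## Parameters that matter

| Parameter | Default | Notes |
|---|---|---|
| `scale_factor` | 1.2 | scaling by 20%, then center-crop back to the input geometry so all outputs share one size |
| `rotation_range_deg` | 50 | angles drawn uniformly on ±50°, exact 0 re-drawn; symmetric range is the conventional reading of "within 50 degrees" |
| `input_size` | 224 px | backbone input; the stub accepts any size |
| `target_n_features` | 10,000 | selection target at full scale; desk-scale runs use proportionally smaller tables and targets |
| RFE `step` | 0.1 | fraction of surviving features dropped per round; one-at-a-time elimination from 100,352 features is computationally absurd |
| `n_levels` | 9 | levels per rule variable (indices 0–8), configurable |
| `zero_frac_threshold` | 0.10 | zero-fraction prefilter; exposed because 0.10 and 0.50 are both defensible readings of the protocol |
| `top_k` | 8 | rule variables kept after correlation ranking |
| `learning_rate`, `batch_size`, `epochs` | 0.001, 32, 100 | Adam with conventional moments (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) |
| `hidden_dim` | 128 | dense pathway width; unstated upstream, exposed in config |
| `train_fraction` | 0.8 | stratified 80/20 split |

## Numerical choices

* **Entropy** is the standard positive Shannon form `−Σ p log₂ p` with
  `0·log 0 = 0`; the decision trees use `rpart`'s information criterion.
* **Gaussian memberships** use `exp(−(x−c)²/(2σ²))`; all membership kinds are
  clamped into [0, 1] and the triangular/trapezoidal kinds have compact
  support. Partition edge levels extend one spacing beyond the observed
  domain so coverage (`max_level μ(x) > 0`) holds on all of it.
* **Fuzzy c-means** minimizes `Σ_i Σ_j w_ij^m ‖x_i − μ_j‖²` (fuzzifier
  `m = 2`) by the standard alternating updates; the per-iteration objective is
  tracked (it must be non-increasing, and the tests assert this), memberships
  row-normalize, points sitting exactly on a center get membership 1, and
  centers are returned sorted so level order is stable.
* **Ties.** Maximal-membership level ties resolve to the lower level index;
  RFE importance ties retain the lower column index; rule conflicts with equal
  degree resolve to the lower class id. All deterministic.
* **Degenerate inputs.** Constant columns produce a single degenerate
  partition level with a warning; single-class labels, empty tables,
  zero-pixel images, and all-zero fuzzy sets raise classed input errors;
  non-finite training loss aborts with a diagnostic rather than continuing.
* **Centroid defuzzification** integrates with the trapezoidal rule on the
  supplied grid.
* **Randomness.** Every stochastic step runs in a private RNG stream seeded
  from a single integer (`withr::with_seed`); no global RNG state is consumed,
  and identical seeds give bit-identical outputs end to end.

## What the synthetic generators emulate — and what they do not

`make_images()` produces blob/texture fields: a pale eosin-like background
with darker nucleus-like Gaussian blobs whose density differs between classes
by `class_separation`. `make_feature_table()` produces Gaussian
class-conditional features with a known informative subset whose class means
differ by `class_separation × noise_sd`. These give the pipeline exactly what
its mechanics need — controllable, statistically separable signal with known
ground truth — and nothing else: no H&E stain statistics, no spatial tissue
morphology, no whole-slide pyramids, no label noise or batch effects. Passing
tests therefore demonstrate that the machinery (counting contracts, recovery
of planted signal, near-chance behavior on shuffled labels) is correct, not
that any particular accuracy will be achieved on real slides.

## Problem sizes used by the tests and the acceptance script

The suite runs desk-scale versions of each experiment: feature tables of
100–300 samples with 20–100 features, selection targets of 5–20, rule bases
over 3–8 variables, and classifier runs of 5–20 epochs at hidden width 16–32.
The acceptance script re-generates the per-class tile counts (481 and 506) at
32 px to exercise the real augmentation code on the full tally, runs 20
selection-recovery replicates, and trains the full pipeline twice (separable
and label-shuffled). Everything completes in about half a minute on one CPU;
the defaults embedded in the functions (224 px, 10,000 features, 100 epochs)
are the full-scale settings.

## Known limitations

* The convolutional backbone is consumed as a published architecture behind an
  interface; executing it needs a deep-learning runtime, without which the
  extractor raises an actionable environment error and only the stub backbone
  runs. Its residual/batch-norm internals are deliberately out of scope.
* Rule bases grow with training-set size (one primitive rule per sample before
  deduplication); very large training sets produce large fuzzification layers.
* Pearson correlation ranks rule variables linearly; a feature informative
  only through a nonlinear relationship could be missed at the `top_k` gate
  even though selection retained it.
* The max-min/centroid inference primitives are provided and tested, but the
  trained classifier uses the weighted-sum defuzzification layer; the two
  agree in spirit, not numerically.
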