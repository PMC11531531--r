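# fuzzyhisto

Binary classification of histopathology tile images (cancer vs. non-cancer)
with a hybrid of deep features and interpretable fuzzy rules. The package is
for computational-pathology practitioners who want the whole chain —
augmentation, feature extraction, feature selection, rule induction, training,
evaluation — as tested, composable R functions that run end to end on seeded
synthetic fixtures, with no external data or GPU.

## The method

Given labeled RGB tiles, the pipeline runs five stages:

1. **Geometric augmentation** — per tile: the original, one copy scaled by 20%
   (center-cropped back), one vertical flip, and three rotations at random
   angles in ±50° (reflection padding), i.e. 6 outputs per input.
2. **Deep feature extraction** — tiles are resized to 224×224, per-channel
   means subtracted, and pushed through a pluggable backbone. With the
   ResNet-50 architecture the flattened final convolutional map gives
   7·7·2048 = 100,352 features per tile; a deterministic `"stub"` backbone
   (grid-pooled intensities, any width) keeps everything runnable without a
   deep-learning runtime.
3. **Recursive feature elimination** — entropy-split decision trees
   (E = −Σ pᵢ log₂ pᵢ) scored over stratified folds; each round drops the
   least-important 10% of surviving features until the target count (default
   10,000) remains.
4. **Wang–Mendel rule induction** — features with >10% zeros are dropped, the
   top 8 by |Pearson r| with the label become rule variables, each is
   partitioned into 9 triangular fuzzy levels, and one rule per training
   sample (antecedent = maximal-membership levels, degree = Π μ, consequent =
   label) is generated, deduplicated, and conflict-resolved by degree.
5. **Fuzzy deep classifier** — a dense pathway (dense → ReLU → dense → ReLU)
   over all selected features runs in parallel with a fuzzification layer
   α_is = Π_j μ_ij(x_sj) over the rule variables; both feed the
   defuzzification/output layer β_sk = Σ_i α_is w_ik (+ dense term + bias) and
   a softmax σ(z)ᵢ = e^{zᵢ}/Σⱼ e^{zⱼ}. Training: Adam, learning rate 0.001,
   cross-entropy, batch 32, stratified 80/20 split.

Evaluation reports the confusion matrix with accuracy, precision,
recall/sensitivity, specificity and F1 = 2TP/(2TP+FP+FN), per class and
macro-averaged.

See `vignettes/fuzzy-histopathology.Rmd` for the design decisions,
numerical conventions, and what the synthetic fixtures do and do not show.

## Worked example

```r
library(fuzzyhisto)

cfg <- pipeline_config(
  seed = 42,
  fixtures = list(n_per_class = 150, n_features = 60, n_informative = 8,
                  class_separation = 6),
  rfe      = list(target_n_features = 20),
  rules    = list(top_k = 8),
  train    = list(epochs = 20, hidden_dim = 32)
)
run <- run_pipeline(cfg)

glance(run$rfe)
#> # A tibble: 1 × 4
#>   n_features_in n_features_out n_rounds final_accuracy
#>           <int>          <int>    <int>          <dbl>
#> 1            60             20       13              1

glance(run$rule_base)
#> # A tibble: 1 × 4
#>   primitive deduplicated conflict_resolved final
#>       <int>        <int>             <int> <int>
#> 1       240          239                 0   239

glance(run$model)
#> # A tibble: 1 × 7
#>   n_features n_rules epochs train_accuracy val_accuracy train_loss val_loss
#>        <int>   <int>  <int>          <dbl>        <dbl>      <dbl>    <dbl>
#> 1         20     239     20              1            1    0.00440  0.00503

run$metrics
#> # A tibble: 3 × 6
#>   class         accuracy precision recall specificity    f1
#>   <chr>            <dbl>     <dbl>  <dbl>       <dbl> <dbl>
#> 1 class_1              1         1      1           1     1
#> 2 class_0              1         1      1           1     1
#> 3 macro_average        1         1      1           1     1
```

Reading it: selection reduced 60 synthetic features to 20 over 13 elimination
rounds with perfect mean fold accuracy (the fixtures are strongly separable by
construction); 240 training samples produced 239 unique fuzzy rules (one
duplicate collapsed, no conflicts); and the classifier reached 100% validation
accuracy on the held-out 60 tiles — all five metrics 1.0 for both classes. On
a label-shuffled control (`cfg$shuffle_labels <- TRUE`) the same pipeline sits
near 50%, which is the point: signal in, signal out; noise in, chance out.

Each result type has `tidy()`/`glance()` methods and `autoplot()` figures
(elimination curve, partition shapes, training curves, confusion heatmap), and
`compare_membership_functions()` re-runs training under triangular,
trapezoidal, and piecewise-linear partitions with a shared seed and split.

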