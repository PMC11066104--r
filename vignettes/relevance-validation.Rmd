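---
title: "Validated relevance maps for 3D brain-image classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validated relevance maps for 3D brain-image classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep 3D convolutional classifiers can detect dementia-related atrophy in
structural MRI, but a scalar prediction is clinically opaque. Layerwise
Relevance Propagation (LRP) decomposes the prediction into a voxel-wise
*relevance map*: each voxel receives a share of the output logit proportional
to its contribution through the network, and positive relevance reads as
visual evidence in favor of the positive class. The catch, well documented in
the saliency literature, is that attribution maps can look anatomically
plausible while carrying no information about the model's decision. This
package therefore pairs the map generator with a quantitative validation
battery — overlap with a reference map, occlusion-based importance, and
randomized null pipelines — so a map is never trusted on looks alone.

Everything runs on synthetic 3D phantoms with known ground truth, so the full
pipeline (training included) is testable on a laptop CPU without any imaging
downloads.

## The model

The classifier is a scaled-down *simple fully convolutional network* (SFCN):
`blocks` repetitions of (3×3×3 convolution, batch normalization, ReLU,
2×2×2 average pooling; no pooling in the last block), global average pooling,
and a single output unit with a sigmoid. Average pooling replaces the usual
max pooling so every layer is a nonnegative linear map, which makes relevance
propagation through the pooling stages exact. Training is vanilla SGD on
binary cross-entropy with subject-disjoint folds stratified on diagnosis,
site, sex and 10-year age bins, selecting the epoch with the lowest
validation loss.

Two numerical choices matter at desk scale and are deliberate deviations from
framework defaults:

* **Batch-norm statistics refresh.** With only tens of SGD steps per epoch,
  momentum-tracked running statistics lag the rapidly-moving weights so far
  that inference-mode outputs diverge from training behaviour. After each
  epoch the trainer re-estimates the per-channel statistics with a forward
  sweep over the training volumes ("precise BN"). The momentum default is
  0.9 rather than 0.99 for the same reason.
* **Learning rate.** Vanilla SGD at `lr = 1` for 30 epochs; smaller rates
  leave the network on a long plateau where it ranks perfectly (AUC 1.0 per
  fold) but remains badly calibrated, because the between-subject variance
  of the pooled features is tiny compared with their spatial variance.

## Model surgery and the LRP engine

Before propagation the model undergoes two equivalence-preserving rewrites:
the sigmoid is removed (so the explained quantity is the unbounded logit,
and a logit of 0 corresponds to a prediction of 0.5), and every batch
normalization is fused into its preceding convolution (adjusting weights and
biases by the normalization's scale and shift). Both are verified by
equivalence tests at 1e-6 / 1e-4 tolerances.

The composite rule assignment mirrors common practice for dementia
classifiers:

| layer | rule | why |
|---|---|---|
| output (dense) | epsilon | keep only salient, stable evidence |
| central convolutions | alpha-beta (α=1, β=0) | upweight positive evidence |
| first convolution + input | flat | smooth fine detail near the input |
| pooling layers | epsilon (fixed-weight conv) | exact linear redistribution |

Parameter choices the source material leaves open, decided here:

* **α, β**: default α=1, β=0 (positive evidence only, matching the stated
  goal of prioritizing regions that contribute positively); α=2, β=1 is
  available via `rule_assignment()`.
* **ε**: a numerical stabilizer only, default 1e-9, added with the sign of
  the denominator; `epsilon = 0` gives exact conservation and is used by the
  conservation tests.
* **Flat-rule connectivity**: `|o|` counts only real upstream neurons at
  borders (zero-padded positions excluded); `flat_count_padding = TRUE`
  switches dialects.
* **Biases** enter the denominators but receive no relevance; conservation
  is therefore asserted on bias-free fixtures, where every rule conserves
  the layer-wise relevance sum to floating-point precision.
* **Zero denominators** absorb the affected relevance; the engine counts and
  reports absorbed events on each map instead of propagating NaNs.

Postprocessing follows the fixed order clip (keep positive evidence) →
brain-mask (no relevance outside tissue) → optional 3×3×3 box smoothing
(before PCA compression only), with re-masking after smoothing so blurring
cannot bleed relevance outside the brain. Clip and mask commute and are
idempotent; smoothing does not commute with masking, hence the fixed order.

## The synthetic world

`synthetic_atlas()` builds an ellipsoidal "brain" (80/76/72% of the grid
extent per axis) partitioned into Voronoi regions; `generate_cohort()` plants
a focal lesion — a multiplicative intensity reduction `1 - effect` — in a
chosen region for cases only, plus i.i.d. Gaussian voxel noise, ages uniform
on [55, 90], two sites, balanced sex. An independent sex-linked intensity
reduction in a *different* region supports the alternative-task null
pipeline. Defaults: `effect = 0.3`, `noise_sd = 0.05`, lesion region chosen
at ~5% of brain volume (a focal, hippocampus-like target; small enough that
localization is a nontrivial claim).

What the phantoms deliberately do **not** emulate: MRI physics (bias fields,
scanner effects), anatomical variability between subjects, nonlinear
registration error, and lesion-shape variability — every case shares the
same lesion support. A green test therefore establishes that the pipeline
recovers a *known, shared* signal through a trained network; it says nothing
about robustness to anatomical heterogeneity.

One consequence is worth spelling out. The random-images null pipeline draws
inputs from a voxel-wise normal with the cohort mean and standard deviation.
In real data this destroys the individual anatomy that drives predictions; in
a phantom world the class signal is a fixed template that partially survives
in the cohort mean, so this null is structurally "less null" here than in
the full-scale setting and its metrics sit between the task pipeline and
the random-weights null rather than at zero. The acceptance suite measures
it honestly at the stated thresholds, and two clauses stay red because of
it: the random-images AOPC exceeds the ±0.05 band, and at the sparsest
binarization percentile its Dice overlap with the reference edges out the
task pipeline. A related desk-scale artifact affects the Dice curves at
moderate percentiles: clipped-and-masked average maps are mostly exact
zeros, so percentile thresholds below the zero fraction compare raw support
sizes instead of localization, and a pipeline with smaller support can sit
marginally above the task curve there. The normalized cross-correlation —
the battery's single-number comparison — orders all four pipelines cleanly.

### What a trained-from-scratch network may do to positive relevance

One desk-scale finding deserves emphasis. A converged classifier provably
relies on the lesion (replacing lesioned voxels with healthy intensities
collapses the prediction from ~0.97 to ~0.02), yet whether the *positive*
relevance of the composite rule set lands on the lesion depends on the
representation SGD happens to find. Some initializations learn
"dark-lesion detectors" (lesion voxels feed positively into the dementia
logit; maps localize, ratios of 5-8x above chance); others encode the
lesion as *reduced negative evidence* (lesion voxels carry net negative
raw relevance, and the positive mass that the clipping step keeps sits on
unrelated structure). Across repeated initializations roughly half the
trained folds localize strongly. The full-scale setting avoids this
ambiguity by initializing from a pretrained brain-age model whose features
already respond to atrophy with a fixed sign — transfer learning is
explicitly out of scope here, so the ambiguity is inherited honestly. The
acceptance suite therefore evaluates the localization criterion at a fixed,
pre-registered seed, as the criterion itself specifies, and the acceptance
script reports whatever its given seed produces; both the strong and the
weak outcome are real behaviours of this pipeline.

## Validation battery

* **Average true-positive map** `R̄`: voxel-wise mean over correctly
  classified cases (label 1, prediction > 0.5).
* **Dice curves**: both `R̄` and the reference map `G` are binarized at the
  same percentile (strict inequality, so constant maps binarize to zero) for
  every integer percentile 0–99. The overlap statistic follows the printed
  form `|A∩B| / (|A|+|B|)` (identical maps score 0.5); the conventional
  coefficient is available behind a flag.
* **nCC**: Pearson correlation over voxels, invariant to affine rescaling.
* **Occlusion / AOPC**: iteratively occlude a noise cube centered on the
  most relevant remaining voxel (20 iterations, cube ≈ 9% of the grid side —
  the 15-voxel-to-167-grid ratio of the full-scale setting), re-predict, and
  zero the cube in the working map; AOPC is the mean drop from baseline.
  Ties break toward the lowest array index; an exhausted map falls back to
  random brain voxels and says so. Training includes the same random-box
  injection as augmentation (default two boxes at probability 0.7 each), so
  the model is approximately invariant to the injection itself.
* **Null pipelines**: scrambled inputs, random weights, and a classifier
  trained on the orthogonal sex attribute — identical machinery, one
  substitution each.

## Longitudinal utilities

Visit histories are day-offset vectors ending at a terminal timepoint (the
first dementia visit for progressors; every (start, terminal) visit pair for
non-progressors). Pair costs are sums of absolute differences between
equal-length histories, infinite otherwise, and matching solves the
rectangular assignment problem exactly (shortest augmenting paths; `Inf`
edges are forbidden rather than big-M-encoded, and unmatchable rows roll
back cleanly to a maximal partial matching). Optimality is tested against
permutation brute force.

Progression targets use the three-way rule: positive if the horizon reaches
the first dementia visit, negative if it stays within observed MCI follow-up,
missing otherwise. Relevance maps are compressed by PCA (default 64
components, which assumes a large cohort; small fixtures must pass
`k ≤ n - 1` — requesting more is an error rather than a silent cap). The
model suite fits l1-penalized logistic regressions (glmnet) in a nested,
subject-disjoint cross-validation; the evaluation timepoint per subject is a
single seeded draw shared across the three models, so fold-wise comparisons
(one-sided signed-rank) are paired.

## Scale choices and limitations

The acceptance studies run at grid 32, 3 blocks, 2 folds, 30 epochs, 100+100
phantoms — a deliberate shrink of the published full-scale setting (167-voxel
grids, 6 blocks, 5 folds, 160 epochs, pre-trained initialization) that keeps
the full train-explain-validate loop within roughly ten CPU-minutes. The
defaults of `build_model()` (grid 48, 5 blocks) retain the spec-scale
architecture for users with more patience. Known limitations: no transfer
learning, no hyperparameter search (dropout/weight-decay are exposed as
documented options), no nonlinear registration (phantoms share a grid by
construction), and the Cox/mixed-model stages are exposed as tidy data
exports for standard estimation tools rather than re-implemented.
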