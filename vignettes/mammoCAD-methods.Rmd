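---
title: "mammoCAD: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mammoCAD: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammoCAD)
```

## The pipeline

mammoCAD implements a classical computer-aided-diagnosis chain for
grayscale mammogram-style images with three labels (normal, benign,
malignant):

1. **median-filter denoising** removes salt-and-pepper impulses while
   keeping edges in place;
2. a small **U-Net** segments the mass region;
3. the predicted mask is applied to the image and a **SqueezeNet**
   (one stem convolution plus eight fire modules) is trained on the
   masked regions; its post-average-pool activations are the feature
   vectors;
4. the SqueezeNet trainer's hyperparameters are tuned by the
   **Archimedes Optimization Algorithm (AOA)**, a population
   metaheuristic, with macro-averaged precision on a validation split
   as the fitness;
5. a **deep belief network** (stacked RBMs pretrained with CD-1, then
   finetuned by backpropagation against a mean squared error on one-hot
   targets) classifies the feature vectors;
6. results are reported as per-class one-vs-rest accuracy, sensitivity,
   specificity and F-measure with an unweighted Average row, under
   stratified 60:40 or 70:30 train/test splits.

Every stage is exposed as an ordinary function returning a classed
object (`unet`, `squeezenet`, `dbn`, `aoa_result`, `eval_report`,
`run_record`) with `print`/`predict` methods, and `run_pipeline()`
drives the whole chain from a single config.

## Synthetic phantoms

Real mammography archives cannot ship with a package, so the test bed
is a phantom generator (`generate_phantom()`).  A phantom is a small
square image on a smooth background (a coarse uniform field bilinearly
upsampled into [0.15, 0.45], imitating low-frequency parenchymal
texture).  A *benign* mass is an isotropic Gaussian blob (peak
amplitude 0.45–0.55, width about 1/8 of the image side); a *malignant*
mass adds 4–8 radial arms whose intensity decays along their length —
the geometric encoding of the clinical rule that irregular, spiculated
margins indicate malignancy.  The ground-truth mask thresholds the
noise-free mass field at half maximum, so the proximal part of each arm
is mass and the outline is irregular.  Salt-and-pepper impulses (exact
0/1 pixels) corrupt a configurable fraction of pixels; clean pixels are
kept strictly inside (0, 1), so the inserted-impulse count is exactly
recoverable — a bookkeeping property the tests rely on.

Two scale choices matter.  First, arm width is at least 1.5 px
(`max(1.5, sigma/3)`): a one-pixel line is majority-voted away by the
pipeline's own 3×3 median filter, so thinner arms would not be a real
image feature at all — just as real spicules span multiple pixels at
diagnostic resolution.  Second, the default phantom is 32×32 (64×64 for
demonstrations): large enough for the three stride-2 poolings of the
feature extractor, small enough that every stage trains in seconds to
minutes on one CPU.

What the phantoms do **not** emulate: radiographic noise physics,
breast-density variation, pectoral muscle and annotation artefacts,
calcifications, or any intensity calibration.  Passing tests show the
pipeline machinery learns and generalizes on geometrically separable
classes; they say nothing about clinical performance.

## Median filter

`median_filter()` replaces each pixel by the median of its
window×window neighbourhood.  The window defaults to 3 — the smallest
standard kernel, sufficient for isolated impulses.  Borders are
edge-replicated so the output shape equals the input shape; this border
policy is a documented choice, made for shape preservation.

## U-Net

The segmenter uses "same"-padded 3×3 convolutions (two per level, ReLU),
2×2 max-pooling with stride 2 per level on the way down, and
nearest-neighbour ×2 upsampling followed by a 2×2 convolution, skip
concatenation with the matching encoder map, and two more 3×3
convolutions on the way up; a final 1×1 convolution produces per-pixel
foreground logits.  Padding (rather than the original crop-style valid
convolutions) makes the output exactly input-shaped.  Depth 2 with 8
base channels is the desk-scale default; both are configurable.

The loss is pixel-wise binary cross-entropy with the foreground term
up-weighted (`pos_weight = 3`, config-exposed).  Mass pixels are only
~10% of a phantom, and the thin spiculation arms are precisely what the
downstream classifier needs; unweighted cross-entropy prunes them from
the predicted masks, after which benign and malignant ROIs become
nearly indistinguishable.  The weighting trades a few false-positive
boundary pixels (harmless under multiplicative masking) for arm recall.
Optimization is Adam over shuffled mini-batches.

`apply_mask()` bridges segmentation and feature extraction: mode
`"mask"` (default) zeroes the background, mode `"crop"` resizes the
mask's bounding box.  An empty mask passes the full image through —
the path taken by normal images, which have nothing to segment.

## SqueezeNet

A fire module squeezes the input through `n` 1×1 filters, then expands
through `4n` 1×1 and `4n` 3×3 filters in parallel and concatenates, so
it always emits `8n` channels.  The network is the stem convolution
plus eight fire modules with stride-2 max-pooling after the stem and
after fire modules 2 and 4 (64 px input → 8×8 map; 32 px → 4×4).  The
head is a 1×1 convolution to `head_width` channels, global average
pooling — the pooled vector is the feature representation — and a dense
softmax layer for training.  The printed head order in descriptions of
this architecture (a 1000-wide fully connected layer *before* average
pooling) inverts the canonical arrangement; we implement conv-head →
average-pool → softmax and expose the head width (desk default 32, the
conventional 1000 available by config).  There is no ImageNet
pretraining: training starts from He-normal initialization on the task
data, single-channel input.

Two trainer details are deliberate.  Convolution biases are initialized
to 0.01 because narrow deep ReLU stacks (squeeze widths of 2–8) die at
zero-bias initialization with noticeable probability.  Training data
can be expanded with the 8 dihedral transforms of each image
(`augment = TRUE` in the pipeline's final training): lesion orientation
is uniformly random, so the symmetry group is an exact label invariance
of the phantom distribution.

## The Archimedes optimizer

Each candidate ("object") carries a position, density, volume and
acceleration.  Per iteration `t` of `tmax`:

- densities and volumes drift toward the best object's values with
  fresh uniform weights;
- the transfer function `TF = exp((t - tmax)/tmax)` switches the regime:
  **exploration** while `TF <= 0.5` (acceleration inherited from a
  random "material": `(den_mr + vol_mr*acc_mr) / (den_i*vol_i)`),
  **exploitation** after (same expression with the best object);
- accelerations are min–max normalized per dimension into [0.1, 0.9];
- positions move by `x + C1*r*accn*d*(x_rand - x)` (exploration) or
  `x_best + F*C2*r*accn*d*(C3*TF*x_best - x)` (exploitation) with the
  direction flag `F = ±1` decided by a uniform draw against
  `p_threshold`, and `d = TF - t/tmax` the shrinking step factor;
- positions are clamped to the bounds and the best-so-far record is
  elitist.

Numerical choices: the acceleration denominator is floored at 1e-12; a
degenerate normalization dimension (max = min) maps everyone to the
midpoint 0.5; user constants default to `C1 = 2, C2 = 6, C3 = 2,
p_threshold = 0.5` and are config-overridable.  Two printed forms of
the update equations required a reading: the exploitation base term is
taken as `x_best` (the variant consistent with the best position
driving exploitation), and the normalization is the standard
`(u-l)*(x-min)/(max-min)+l` form, which is the only one that actually
realizes the stated [0.1, 0.9] range.

For hyperparameter tuning the search space has four dimensions —
learning rate (log scale), batch size (integer), epochs (integer),
weight decay (log scale) — and the fitness is macro-averaged precision
on a stratified validation split (20% of the training set by default).
The learning-rate bounds, [3e-4, 5e-3], are confined to the trainer's
stable region: above ~5e-3 the desk-scale network reliably falls into a
uniform-output attractor, so admitting such rates only wastes
evaluations.  The search is warm-started: the default trainer
configuration seeds one object of the initial population, which —
combined with elitism — guarantees the tuned result is never worse than
the default on the tuning fitness.  Candidates are evaluated without
augmentation (for speed); the final model is trained with it.  As a
second guard, the pipeline checks that the final model fits its own
training set (the phantom classes are separable, so failing to reach
the configurable `min_train_accuracy`, default 0.85, signals a poor
optimization basin) and retrains at half the learning rate, up to three
times, deterministically.

## Deep belief network

Each RBM stores a visible×hidden weight matrix `W`, visible bias `a`
and hidden bias `b` (the equations as printed swap the bias names; we
assign them so each conditional is dimensionally coherent).  CD-1
samples `H1 ~ P(H1|V1)` and `V2 ~ P(V2|H1)`, takes `H2` as
probabilities, and updates with the difference of batch-averaged outer
products.  Stacking is greedy; mean-field probabilities (never samples)
feed the next layer and are used at inference, so prediction is
deterministic.  Finetuning backpropagates the mean squared error
between a linear output layer and one-hot targets (the stated
objective; not cross-entropy), with argmax decisions and ties broken by
class order.

The pipeline defaults use a gentle CD learning rate (0.02): hot CD
pretraining (0.1) saturates the hidden units and measurably *hurts*
subsequent finetuning on low-dimensional feature inputs, while 0.1
remains the right scale for the classic bars-and-stripes
reconstruction benchmark.  SqueezeNet features are min–max normalized
to [0, 1] on training statistics before entering the DBN, matching its
sigmoid visible units.  Mean-squared-error descent through sigmoid
stacks can sit on long plateaus (including partial two-class
solutions) before converging, so the pipeline finetunes for 300 epochs
by default and deterministically extends training (up to three more
rounds) while the model has not yet fit its separable training set —
the same under-convergence principle as the feature-stage guard.

## Evaluation

Per-class metrics are one-vs-rest: accuracy `(TP+TN)/total`,
sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F-measure from
per-class precision and sensitivity.  One-vs-rest accuracy is the only
reading under which a per-class accuracy column is well defined; the
Average row is the unweighted mean.  Values are displayed as
percentages rounded half-up to two decimals; raw fractions stay in the
`"raw"` attribute.  Zero denominators yield 0 with a warning.  Split
ratios are training-share first: "70:30" puts 70% of each class in the
training set, so 1000 records with 300/350/350 per class give exactly
700/300.

## Problem sizes and determinism

Default study conditions: 30 phantoms per class (90 total) at 32×32
with 5% impulse noise; a 60:40 stratified split; U-Net depth 2 /
8 base channels trained 40 epochs; SqueezeNet fire widths
4,4,4,4,8,8,8,8 with a 32-wide head; AOA with 5 objects and 5
iterations (31 fitness evaluations); DBN 32→24→12→3.  A full
`run_pipeline()` takes a few minutes on one CPU.  Every stochastic
stage derives its own seed from the global seed and a stage label
(`derive_seed()`), and trainers restore the caller's RNG state, so runs
are bit-reproducible end to end.

## Known limitations

- The networks are desk-scale; nothing here is sized for real
  mammograms, and the phantom classes are far easier than clinical data.
- The pipeline's accuracy rests on the segmentation preserving margin
  structure; on data where lesions are not brighter than background the
  ROI-masking handoff would need rethinking.
- AOA tuning evaluates each candidate once on a single validation
  split; k-fold fitness would be less noisy but multiplies cost.
- The DBN consumes only the pooled feature vector; no spatial
  information survives the global average pooling.
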