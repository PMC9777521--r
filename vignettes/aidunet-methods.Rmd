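---
title: "AID-U-Net: model, design choices and desk-scale validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AID-U-Net: model, design choices and desk-scale validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aidunet)
```

## The model

AID-U-Net is a U-Net-style encoder/decoder for semantic segmentation of
biomedical images whose distinguishing feature is a *nested excursion*
attached at the bottom of the network. A configuration is written
AID-U-Net(K, d):

* a **direct contracting path** descends `K` levels (each level: a block of
  two padded 3×3 convolutions, batch normalization after the first,
  ReLUs and dropout; 2×2 max-pooling between blocks);
* from the bottleneck a **sub-expansive path** ascends `d` levels
  (2×2 stride-2 up-convolution halving the channels, concatenation with the
  direct contracting feature at the same level, then the two-convolution
  block);
* a **sub-contracting path** descends the same `d` levels back to level `K`;
* the **direct expansive path** then ascends from the sub-contracting
  output to level 0, with the usual skip concatenations from the direct
  contracting path;
* a 1×1 convolution and per-pixel softmax produce class probabilities.

Filter counts follow the usual ladder `2^(nf + level)`; the reference
configuration uses `nf = 5` (32 filters at the top). `d = 0` degenerates to
a conventional U-Net of depth `K`, and validity requires `d ≤ K` — the
sub-path can never be longer than the direct path. Because every axis is
halved `K` times, each input-patch axis must be divisible by `2^K`.

Two consequences of splitting a total depth `N = K + d` this way:

* **Complexity.** Per-level cost grows geometrically with ratio 2, so a
  depth-`N` U-Net has worst-case order `2^(N+1) − 1`, while AID-U-Net(K, d)
  has `s1 + s2 = (2^(K+1) − 1) + (2^(K+1) − 2^(K−d)) = 2^(K+2) − 2^(K−d) − 1`,
  strictly smaller whenever `d ≥ 1`. `complexityUNet()` and
  `complexityAid()` compute these closed forms; for `(N, K, d) = (5, 3, 2)`
  they give 63 vs 29.
* **Parameters.** The deepest (and widest) levels dominate the parameter
  count, and the nested split visits them with narrower decoders.
  `planLayers()` + `countParameters()` make this exact: with `nf = 5`,
  3-channel input and 2 classes, AID-U-Net(3, 1) has 3,386,882 trainable
  scalars and AID-U-Net(2, 2) has 924,130, versus 7,763,074 for the same
  planner's U-Net(4).

### Conventions behind the parameter count

The counting convention is part of the model definition, so we state it
explicitly; it was fixed once and the runnable models are materialized from
the same layer graph, so planned and actual counts agree by construction
(and by test):

* two 3×3 convolutions per block, each with a bias;
* **one** batch-normalization per block, after the first convolution (the
  batch-normalization contributes a trainable scale/shift `(γ, β)` pair per
  channel; running statistics are not trainable and are not counted);
* expansive-type blocks are entered through a 2×2 (2×2×2 in 3D) stride-2
  transposed convolution with bias that halves the channels, followed by a
  two-input concatenation;
* sub-expansive blocks receive skip concatenations from the direct
  contracting path at their level; the direct decoder up-convolves directly
  from the sub-contracting output (no extra bottleneck concatenation);
* the head is a 1×1 convolution with bias.

We considered the plausible alternatives (a second normalization per
block; concatenating the bottleneck with the sub-contracting output before
the decoder; single-convolution expansive blocks). Only the convention
above reproduces the published reference counts for both AID-U-Net(3, 1)
("3.4 M") and AID-U-Net(2, 2) ("924 K") — the latter exactly, at 924,130 —
so it was adopted throughout. Counts are reported in M/K at two
significant figures when pretty-printed.

Concatenation (rather than addition) is also what keeps feature variance
stable: the per-channel variance of a concatenated tensor equals that of
its inputs, whereas adding two independent inputs doubles it. This merge
contract is asserted numerically in the tests.

## The engine

No deep-learning framework is assumed: the package ships its own small
computation-graph engine in base R. Convolutions are evaluated as BLAS
matrix products on gathered im2col matrices; transposed convolutions write
each of the `2^dims` kernel taps to its output parity class; max-pooling
tracks argmax indices for the backward pass; batch normalization uses batch
statistics in training and running statistics (momentum 0.9) in inference.
All gradients are hand-derived and were verified against central finite
differences (worst relative error ~2×10⁻⁷ across every layer type).
The same code paths serve 2D and 3D; only the index sets differ.

Numerical choices:

* weight initialization is variance-scaling (fan-in) Gaussian, seeded; the
  transposed convolution uses fan-in `c_in` since each output position sees
  exactly one kernel tap;
* the optimiser is Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e−8) with default
  learning rate 1e−3 — chosen for reliable convergence on small fixtures;
  plain SGD is available;
* the generalized dice loss adds a smoothing constant ε = 1e−5 to
  numerator and denominator to guard empty intersections; on the worked
  4-element example this perturbs the loss by far less than 1e−4;
* inverse-squared-area dice weights are recomputed per batch from the
  ground truth and treated as constants in the gradient (the standard
  convention); a class absent from a batch gets weight 0;
* max-pooling and argmax decisions break ties toward the first candidate,
  making runs bitwise reproducible under fixed seeds and thread counts;
* dropout masks, shuffling and weight draws all flow from the two explicit
  seeds (model seed, training seed).

## Pre-processing

Patch extraction adapts arbitrary image sizes to the fixed network input.
When the image tiles exactly, no crop is applied. Otherwise the crop
window (per-axis `floor(extent/patch)·patch`) is centred on the foreground
centroid, clamped to the image, with ties broken toward the top-left —
this keeps compact objects inside patches and is fully reproducible. The
automatic rule can be replaced by an explicit crop override, since useful
crop sizes are ultimately dataset-specific. If the foreground bounding box
cannot fit in any single patch, cropping cannot prevent object loss; the
full image is kept and covered by the smallest number of patches at a
uniform stride, flagged as overlapping. Foreground discarded by a crop is
counted and surfaced as a warning.

Augmentation (quarter-turn rotations, axis reflections, small random
translations with reflection padding) is applied after patch extraction —
the natural place once patches, not images, are the training unit — with
identical transforms for image and mask and nearest-neighbour (i.e. exact
index) mask handling. Prediction reverses the mapping: per-patch class
probabilities are averaged where patches overlap, argmax is taken, and the
result is placed at the crop offset with everything outside labelled
background.

## Evaluation metrics

`segmentationScores()` reports per-class precision, recall, F1, IoU and
dice plus global accuracy, mean (per-class) accuracy, mean IoU,
ground-truth-frequency-weighted IoU and mean boundary-F1. Boundary pixels
are region pixels with a face-adjacent neighbour of another class (the
image border is not a boundary), and boundaries are matched within a
Euclidean tolerance defaulting to 0.75% of the image diagonal — a
widespread convention, exposed as `bfTolerance`. Classes absent from both
masks are excluded from the means rather than scored zero, so fixtures
with missing classes stay comparable. For binary masks F1 and dice
coincide (`2TP/(2TP+FP+FN)`), and published "IoU" may mean either the
foreground-class IoU or the class mean — both are emitted. Confusion
overlays use the fixed map TP→cyan, FP→magenta, FN→yellow, TN→black.

## Synthetic fixtures: what they do and do not show

`makeDataset()` renders seeded 2D (RGB) and 3D (multi-channel) samples:
1-3 superellipse blobs with low-frequency radial boundary perturbation
(smooth ellipsoids in 3D), distinct foreground intensity on a flat,
gradient or smoothed-speckle background, additive Gaussian noise
(sd 0.05), and a per-sample foreground fraction confined by rejection to
1-15% — the heavy class imbalance that motivates the dice loss. Each
sample draws from its own `(seed, index)`-derived stream, so any subset
regenerates identically.

These fixtures reproduce the *statistical shape* of small-lesion
segmentation tasks (compact objects, imbalance, texture, noise) but not
specular highlights, anatomy, modality physics or annotation noise.
Passing the end-to-end tests therefore demonstrates that the
architecture, losses, gradients and pipeline are correct and can learn a
non-trivial segmentation — not that any particular clinical performance
level would be attained on real data.

## Problem sizes used in the checks

The package's own validation runs at desk scale, chosen so the entire
suite executes comfortably on one CPU: the end-to-end training check uses
AID-U-Net(2, 1) with `nf = 4` (16 base filters), dropout 0.1, batch size
4, Adam at 1e−3, on 64 synthetic 64×64 RGB samples (48 train / 16
validation) for 10 epochs, and requires the validation foreground IoU to
exceed both the all-background baseline (IoU 0) and 0.5. Under the
package seeds this run reaches validation IoU ≈ 0.99 within 10 epochs.
Parameter-count and complexity checks use the reference `nf = 5`
configurations; 3D checks use narrower widths (`nf = 2-3`) and smaller
extents, which exercise identical code paths.

## Known limitations

* Exactly one sub-excursion is instantiated; architectures with several
  stacked excursions are not expressible.
* No automatic search over `(K, d)`; good depths remain an empirical,
  per-dataset choice.
* No pre-trained backbones; weights always start from seeded random
  initialization.
* The engine is CPU-only and single-device; it favours clarity and exact
  reproducibility over throughput, and large-scale training is out of
  scope.
* Intensity augmentation and elastic deformations are not provided.
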