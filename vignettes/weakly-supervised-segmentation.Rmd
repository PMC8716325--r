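---
title: "Learning lesion boundaries from circumscribing annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning lesion boundaries from circumscribing annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical lesion annotations on screening mammograms are hand-drawn loops
that *circumscribe* the lesion: they enclose the true lesion support plus a
band of healthy tissue whose width varies from case to case. A
segmentation model trained to reproduce such masks inherits their
imprecision. `latentcadx` implements a weakly-supervised joint
classification–segmentation model whose objective treats the two sides of
the annotation boundary separately, together with the evaluation metrics
needed to characterize predictions against imprecise reference masks, a
calibration pipeline for raw 16-bit scans, and a seedable phantom
generator so every stage is testable on one CPU without any imaging
download.

## Model

The network is a residual convolutional encoder shared by three heads:

* a **classification head** (global average pooling plus a dense layer)
  producing the patch-level lesion probability $y$;
* a **region-proposal (RPN) head**, a $1\times1$ convolution over the
  deepest $g \times g$ feature map producing a per-cell two-way softmax of
  lesion presence, used only to pretrain the encoder;
* a **decoder** of transposed-convolution blocks that doubles resolution
  at every step, concatenates the matching-resolution encoder feature
  (skip connections), and ends in a per-pixel sigmoid, giving a
  probability mask $M$ at input resolution.

Every interior convolution is followed by batch normalization and a ReLU;
residual networks rely on this normalization, and at desk scale it is the
difference between a trainable and an untrainable model under plain SGD.
Frozen parameter groups run their batch norms in evaluation mode (running
statistics, no updates), so a frozen group is bit-stable through a
training phase. The configuration (`seg_model_config()`) pins the shape
arithmetic: `input_size / 2^stages = deepest_grid` and
`decoder_blocks = log2(input_size / deepest_grid)`; the scan-scale variant
(256 px input, 8×8×2048 deepest map, 5 decoder blocks) and the 64-px
miniature used throughout the tests share one code path.

## Objective

For a patch with label $\hat y$, annotation mask $\hat M$ and outputs
$(y, M)$, with $N_{inb} = \sum_i \hat M_i$ and
$N_{oob} = \sum_i (1 - \hat M_i)$:

$$
L = \alpha\,\mathrm{CE}(y, \hat y)
  + \beta\,\frac{1}{N_{inb}}\sum_i \hat M_i\,(\hat M_i - M_i)^2
  + \gamma\,\frac{1}{N_{oob}}\sum_i (1-\hat M_i)\,M_i^2 .
$$

The in-bounds term is the mean squared shortfall inside the annotation;
the out-of-bounds term is the mean squared probability that egresses
beyond it. Batches reduce by the mean of per-patch totals. Degenerate
regions ($N_{inb}=0$ on negative patches, or $N_{oob}=0$) contribute zero
for that term, so negative patches train only the classification and
egress terms. Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ before
logarithms.

Defaults are $\alpha = 2$, $\beta = 1$, $\gamma = 0.5$ for joint training
and $\beta = \gamma = 1$ with no classification term during the decoder
warm-up. We note an internal tension in this configuration: the stated
prioritization of the objective is $\beta < \gamma < \alpha$ with a
"heavy" egress penalty, which the values $\gamma = 0.5 < \beta = 1$ do not
satisfy (the transposition $\beta = 0.5, \gamma = 1$ would). We ship the
configured values as defaults and expose all three weights; the
consequences are discussed under *What the desk-scale experiment shows*.

## Training procedure

`latentcadx()` in its default mode runs the full recipe:

1. **Pretraining** (`pretrain_rpn()`): a classification + RPN model is
   trained on patch labels and per-cell objectness targets (a cell is
   positive when at least 10 % of it is annotated — a configurable,
   recorded choice).
2. **Weight transfer** (`transfer_weights()`): the encoder (and heads,
   where present) are copied into the full architecture; the decoder stays
   freshly initialized and the transfer report records copied vs fresh
   groups.
3. **Warm-up**: for `warmup_epochs` every transferred weight is locked
   (parameters and batch-norm statistics) and only the decoder trains,
   under $\beta = \gamma = 1$ and no classification term.
4. **Joint fine-tuning**: everything unfreezes (the RPN head is
   discarded), the weights switch to $(\alpha, \beta, \gamma) = (2, 1,
   0.5)$, and training continues until `max_epochs` or until the
   validation loss changes by less than $10^{-6}$ between consecutive
   epochs (patience 1; both readings are configurable). The best
   validation checkpoint is kept.

The optimizer is SGD with momentum 0.9 (no weight decay), initial rate
0.001 halved every 10 epochs at scan scale, batch size 32. The validation
split is 20 %, stratified by label at a fixed seed. During warm-up the
classification head is frozen along with the encoder (the transferred
weights are locked as a unit) and early stopping monitors the total loss.

Two reference modes share the architecture: `from_scratch_alpha` (random
initialization, $\alpha=\beta=\gamma=1$, no staging) and
`plain_mse_baseline` (random initialization, classification plus an
undivided full-image MSE against the annotation — no in/out-of-bounds
decomposition).

**Desk scaling.** The test and demo runs divide every stage length by
five — pretrain 10, warm-up 3, at most 20 joint epochs, halving period
2 — and raise the learning rate to 0.1, appropriate for a miniature
normalized network that sees a few hundred SGD steps in total. The
full-desk experiment uses 300 training and 100 test 64-px patches
(3 negatives per positive), which trains both models in about 3–4 minutes
on one CPU core.

## Evaluation metrics

With prediction $P$ (the mask binarized at 0.5, ties to positive) and
annotation $A$:

* $\mathrm{IOP} = |P \cap A| / |P|$ — the fraction of predicted pixels
  inside the annotation (pixel-level specificity);
* $\mathrm{IOA} = |P \cap A| / |A|$ — the fraction of the annotation
  covered (pixel-level sensitivity);
* $\mathrm{IOU} = |P \cap A| / |P \cup A|$, with the harmonic identity
  $\mathrm{IOU} = (1/\mathrm{IOP} + 1/\mathrm{IOA} - 1)^{-1}$ whenever the
  intersection is nonempty (used as an internal cross-check).

High IOP with low IOA is the signature of a prediction tighter than its
circumscribing annotation. **Confused pixels** counts mask probabilities
in the inclusive band $[0.5 - \epsilon, 0.5 + \epsilon]$, $\epsilon = 0.2$
by default, quantifying boundary uncertainty. Detection **AP at IOU
thresholds** 0.3/0.5/0.7 treats each patch's mask as one detection ranked
by the classification confidence, with all-points interpolation;
classification metrics are F1/precision/recall at 0.5, cut-point-grouped
average precision, and the rank-statistic ROC-AUC. Empty-set conventions
(recorded in each report): an empty prediction scores IOP 1 against an
empty annotation and 0 otherwise, symmetrically for IOA, and the IOU of
two empty masks is 1, so negative patches cannot poison positive-patch
means. All of these are verified against brute-force loop oracles in the
test suite.

On synthetic data the report adds a **recovery block**: the mean IOU of
predictions against the *hidden true lesion* next to the same quantity for
the coarse annotations, which is the direct desk-scale probe of latent
lesion recovery.

## The phantom generator

`generate_patch()` renders a textured background (broadly smoothed
Gaussian noise rescaled into [0.1, 0.4]), then either a **mass** — a
star-convex blob whose radius is modulated by low-order harmonics
$r(\theta) = r_0(1 + \sum_{k=2}^{5} a_k \sin(k\theta + \varphi_k))$ — or a
**calcification cluster** of small bright specks, lifts lesion pixels by
`contrast`, and adds per-pixel Gaussian noise. The annotation is the
convex hull of the true support dilated by a disc whose radius is drawn
uniformly from `annotation_margin_range` (at least 1 px, so annotations
*strictly* circumscribe); a calcification cluster gets a single hull
around all specks, mimicking the coarsest style of hand-drawn loop.
Patches are lesion-centered with lesions occupying a substantial fraction
of the frame, as they do when patches are sampled at the annotation's
center of mass. Identical `(spec, seed)` pairs are bit-identical; margins
that would leave the frame are clipped with a warning.

What the phantom deliberately does **not** emulate: radiographically
realistic parenchyma, bright non-lesion distractor structures, diffuse
lesion margins, pectoral muscle, or scanner physics. Its lesions are
sharp-edged and easily separable from the background, which makes
classification saturate and makes the *annotation itself* (bright blob
plus a learnable dilation) an easy regression target — a property with
direct consequences below.

## What the desk-scale experiment shows

The acceptance experiment trains the staged model and the plain-MSE
baseline on the same phantom cohort and compares IOP, IOA, confused
pixels, recovery and the egress fraction (predicted-positive pixels
outside the annotation). Two findings are robust across seeds and
schedules at this scale:

* The staged model produces **fewer confused pixels** than the baseline:
  the per-region objective commits pixels decisively.
* The staged model **fills its annotations** (IOA near 1) while the
  baseline under-segments toward lesion cores. This is the opposite of
  the tight-prediction signature, and it follows from the weighting
  arithmetic: with annotations covering a fraction $f < 2/3$ of the
  patch, the per-pixel in-bounds pressure $\beta / N_{inb}$ exceeds the
  per-pixel egress pressure $\gamma / N_{oob}$ for the default
  $(\beta, \gamma) = (1, 0.5)$, so the pixelwise optimum under this
  objective covers the annotation plus the modal margin. A phantom in
  which the dilation is learnable therefore rewards annotation-filling;
  the transposed prioritization $\beta < \gamma$ shrinks but does not
  reverse the gap at desk scale. The tight-prediction behaviour on real
  data evidently rests on the dilation *not* being learnable there —
  hand-drawn margins are annotator noise, not an image feature — which is
  precisely the aspect of real data the sharp-edged phantom does not
  reproduce.

The corresponding directional test expectations are asserted as stated
and left failing rather than weakened; the numbers they compare are
recomputed by `scripts/acceptance.R` on every run.

## Calibration pipeline

Raw 16-bit scans map to optical density through a pluggable monotone
`od_map` (linear `raw / 65535 * 3` by default, standing in for
scanner-specific curves that live with the source archives), clip below
0.05 to 0 and above 3.0 to 3.0, normalize by 3.0, zero-pad to a
4000 × 6000 canvas and downsample ×0.25 — by exact block-mean area
averaging when `1/factor` is an integer. Clipping precedes normalization;
the pipeline is pixelwise monotone and never crops silently. Positive
patches are cut at the annotation's center of mass (shifted inward at
borders); negative patches come from a raster-order sliding window that
discards frames with under 25 % tissue (intensity > 0.05). Augmentation
applies one rotation drawn from ±15° (bilinear for the image,
nearest-neighbour for both masks, preserving binarity and
circumscription), an optional random crop resized back, and additive
Gaussian noise on the image only. Coordinates are 0-based in file paths
and 1-based matrices internally; windows are half-open.

## Numerical and design choices

* Column-major `(H, W, C, N)` tensors; GEMM-backed im2col convolutions in
  C++ (the only compiled code), exact to the reference loop
  implementations and to finite-difference gradients at $10^{-4}$.
* He-normal initialization; the final mask bias starts at −2 so an
  untrained model predicts background under class imbalance.
* The RPN's two channels form a per-cell softmax pair; only the lesion
  channel enters the pretraining cross-entropy.
* Batch-norm buffers use momentum 0.1 and travel with weight transfer.
* All randomness (generation, splits, shuffling, initialization,
  augmentation) flows from explicit integer seeds through private RNG
  streams that restore the caller's RNG state; equal seeds give
  bit-identical patches, manifests and fits on a single CPU thread.

## Limitations

The phantom's tractability is a feature for testing and a limitation for
inference about real mammograms: passing tests demonstrate the
correctness of losses, schedule mechanics, metrics and plumbing, not
clinical segmentation quality. The miniature architecture (tens of
thousands of parameters) is three orders of magnitude below the
scan-scale configuration, and the desk schedule is a five-fold
compression of the published recipe. Scan-scale training requires GPU
resources and the external imaging archive, both outside this package's
scope.
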