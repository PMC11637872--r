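---
title: "Detecting feature cells in powdered-herb micrographs: models, augmentation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting feature cells in powdered-herb micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(microdetect)
```

## The problem

Authentication of powdered medicinal herbs by microscopy rests on spotting
*feature cells* — stone cells, fibers, vessels, cork cells, oil cells,
starch granules — whose presence identifies a species. Annotated micrograph
collections for this task are scarce, severely class-imbalanced (a handful
of images for rare cell types against thousands for common fibers), and the
cells themselves are small, unevenly scattered, frequently cut off by the
frame edge, and blurred by the optics and the grinding process.
`microdetect` implements a complete, self-contained detection stack for
this setting: a synthetic-slide generator that reproduces those statistical
difficulties, a split-recombine augmentation with exact label remapping, a
compact three-scale anchor detector with two channel-attention operators, a
squared-error grid loss with IoU-valued confidence targets, the standard
detection metric suite, and a five-fold cross-validation protocol with
box-cluster majority voting.

## Synthetic slides

Real collections of this kind are not redistributable, so every stage is
exercised on generated data. `slide_spec()` fixes the study conditions;
`generate_slide(spec, i)` is a pure function of `(spec$seed, i)`, so a
dataset is reproducible image by image and generation order is irrelevant.

Cells are rendered as rotated, textured ellipses on a noisy bright
background. Each class has a deterministic style (hue spread around the
color circle, an aspect-ratio family, and a speckle/stripe/ring texture).
Default conditions mirror the reference annotation profile shipped as
`cell_profile`: nine classes whose image counts span 13 to 7555 (11,060
images, 12,840 boxes in total), zero to five cells per image, whole-image
Gaussian blur up to sigma 1.5 px, and a quarter of the cells truncated by
the frame so only their visible part is annotated (the label box always
tightly encloses the visible mask pixels, which keeps the box invariants
closed under truncation). The minor semi-axis of a cell is floored at 4 px:
thinner structures would be unresolvable at the rendered scale and would
make labels meaningless rather than hard.

What the generator does *not* emulate: real stain chemistry and optics,
structured debris, overlapping tissue fragments, and annotation error.
Passing tests on synthetic slides therefore demonstrate the correctness and
trainability of the pipeline, not field accuracy on real micrographs.

## Split-recombine augmentation

`split_recombine_pair()` cuts two annotated images at `floor(W/2)` into
left and right halves and stitches the four ordered mixed-source
combinations — `(aL,bR)`, `(bL,aR)`, `(aR,bL)`, `(bR,aL)` — which is the
unique enumeration producing exactly four outputs that all mix sources and
all differ from both originals. A box crossing the cut is clipped to each
side and kept where its retained-area fraction is at least
`clip_keep_fraction` (default 0.2): partially visible cells are a feature
of real edge-truncated micrographs, not noise, so remnants are kept rather
than discarded. All remapping is exact rational arithmetic on normalized
coordinates — no resampling — so a label never drifts from its pixels, and
`recombine(split(img))` reproduces the input bit for bit. Rotations are
restricted to 90-degree multiples for the same reason: axis-aligned boxes
stay tight. `balance_dataset()` drives the pair sampler toward the
currently rarest class (measured in *box* counts, since detection training
consumes boxes, not images) until every class reaches `balance_ratio`
times the most frequent class or the pair budget runs out, in which case
it reports a warning status rather than failing.

## Attention operators

Two purely channel-wise gates are provided. The squeeze-excitation block
pools each channel to its mean, passes the statistic through a bias-free
bottleneck (`C -> C/r -> C`, ReLU then sigmoid, `r = 16` with the width
floored at 1 for narrow maps) and rescales each channel by the resulting
weight. The efficient-channel-attention block replaces the bottleneck with
a single bias-free 1-D convolution across the channel statistic whose
kernel length is the odd integer nearest to `log2(C)/2 + 1/2` (ties and
even values resolved upward, floored at 1). Because both operators multiply
each channel by a scalar in (0,1), they preserve shape, never amplify, and
commute with any spatial permutation — properties the test suite asserts
directly. In the detector, squeeze-excitation sits after the two shallow
backbone stages (where morphological contrast lives) and efficient channel
attention on the three fused neck outputs feeding the heads.

## The detector and its loss

The network is a compact single-stage detector: five strided 3x3
convolution stages with residual refinement blocks (SiLU activations, no
normalization layers at this scale), an SPPF block (three chained stride-1
max-pools concatenated and fused 1x1) at the deepest stage, top-down then
bottom-up fusion by channel concatenation and 3x3 convs, and 1x1 heads
emitting, per anchor and grid cell, `(t_x, t_y, t_w, t_h, t_conf, class
logits)` at strides 8, 16 and 32. Channel widths default to (8, 16, 32,
48, 64) — sized for CPU training. Anchors default to 9 k-means clusters of
the training boxes' pixel dimensions, assigned by area to the three
scales. All forward/backward computation is implemented in the package
(im2col GEMM convolution kernels plus a small reverse-mode tape), and
analytic gradients are verified against finite differences in the tests.

Decoding: box centers are `sigmoid` offsets within the responsible cell;
extents are `(2*sigmoid)^2` times the anchor size (caps growth at 4x);
class probabilities are per-class sigmoids. The confidence channel is
**linear**: the loss is a plain squared error against its target, and
inference clamps it to [0, 1]. An earlier sigmoid-decoded variant
saturated near zero on rare-class cells early in training and could not
recover within a short epoch budget; the linear channel has a constant
gradient and does not exhibit the pathology.

The loss has three parts, summed (not averaged) over responsible
anchor-cells: squared errors on the decoded normalized box coordinates
(`x, y, w, h` — deliberately *without* the classic square-root transform
on `w, h`; a `box_mode = "ciou"` switch replaces this term with
`1 - CIoU`), squared errors of class probabilities against the one-hot
label, and squared confidence error whose target on a responsible cell is
the live IoU between the decoded predicted box and its ground truth
(treated as a constant when differentiating — the usual moving-target
convention; `conf_targets` lets callers freeze it, which is how the
finite-difference tests obtain an exactly differentiable surface) and zero
elsewhere, down-weighted by `lambda_noobj = 0.5`. Component weights
default to 0.05 / 0.5 / 1.0 (box / class / confidence) and are fully
configurable; the desk-scale benchmark raises the box and class weights to
0.5 / 1.0, which substantially accelerates localization learning in short
schedules. A ground-truth box is assigned to the grid cell containing its
center at every scale where an anchor matches its shape within a 4:1
ratio, with a best-ratio fallback so no box goes unassigned.

Training uses Adam with linear warmup over the first 10% of steps and
cosine decay to a tenth of the peak rate; gradients are exact sums over
the batch. The reference protocol is 100 epochs, learning rate 0.001,
batch 16; the desk-scale defaults shipped here are 8 epochs, batch 4-8,
and learning rate 0.002, chosen so five-fold training completes in minutes
on one CPU core.

## Evaluation

`map_suite()` reports per-class precision/recall (at the operating score
threshold, IoU 0.5), per-class AP, mAP@.5 (all-point interpolation) and
mAP@.5:.95 (101-point interpolation averaged over IoU 0.50:0.05:0.95),
with greedy highest-score-first one-to-one matching. Classes with no
ground truth are excluded from the means. Score is objectness times the
best class probability; NMS is class-wise greedy with ties broken by box
coordinates so the result is independent of input order.

MCC and ROC curves need true negatives, which pure detection does not
define. The package adopts a detection-adapted convention: the model's
finite decision space is its anchor-cell grid, and
`TN = total anchor-cells - (number of ground-truth boxes + FP)` — cells
neither responsible for an object nor producing an above-threshold
detection. The ROC sweeps score thresholds 0.1 to 1.0 in steps of 0.1,
with endpoints (0,0) and (1,1) closing the trapezoid integral; a detector
emitting nothing at every threshold is flagged degenerate rather than
silently scored. These conventions are this package's choice and are
stated here because MCC/AUC values are only comparable under the same
convention.

Numerical notes: 0/0 precision is 0 and 0/0 recall is 1 (vacuous); a zero
factor in the MCC denominator gives 0; the 101-point recall grid is
compared with a 1e-9 guard so exact-recall fractions are not lost to
floating-point representation.

## Cross-validation and voting

`run_experiment()` wires the full protocol: generate (optional), split
8:2 stratified by each image's majority class (largest-remainder
allocation makes the test count exact), five folds of sizes differing by
at most one, per-fold training with balancing augmentation applied to the
fold's *training* images only (augmented derivatives of an image never
cross a partition boundary — applying augmentation before splitting would
leak near-duplicate halves), per-model test predictions, and box-cluster
majority voting: detections from all models cluster greedily by
descending score at IoU 0.5, and clusters backed by at least 3 of the 5
models are emitted with the majority class and the mean box and score of
the majority-class members. This reduces to plain label voting when each
model emits one box, is idempotent, and is the identity for a single
model with `min_votes = 1`.

## The desk-scale benchmark

`desk_experiment_config()` fixes the package's reference benchmark: two
classes, 120 slides at 128 x 128 px, 1-3 cells per image, class weights
0.65/0.35, blur sigma up to 1, an 8:2 split, five folds x 8 epochs, and
balancing augmentation with a 70-pair budget (class ratio target 0.75). These problem sizes are the
package's own choice of a CPU-tractable configuration; the acceptance
script (`scripts/acceptance.R`) runs exactly this benchmark and writes the
resulting ensemble metrics as JSON. On it, the voted ensemble reaches
mAP@.5 well above 0.5, and enabling augmentation plus both attention
blocks consistently outperforms the bare detector — the same direction the
full-scale ablation of the underlying method reports. Headline figures
from the original full-scale study (mAP@.5 around 0.89 on 11,060 real
micrographs trained for 100 GPU epochs) are out of reach of this
synthetic, CPU-scale setting and are not claimed.

## Known limitations

* The renderer's cells are convex blobs; real feature cells have walls,
  lumens and pits that the texture families only gesture at.
* No batch normalization; very deep or wide configurations of this
  architecture would train poorly without it.
* The CIoU box mode computes its cell-level gradients by central
  differences (responsible cells are few, so the cost is negligible), and
  the aspect-ratio coupling term treats its weight as constant.
* Single-image forward passes only; there is no batched tensor path, so
  throughput is linear in image count.
* MCC/AUC depend on the detection-adapted TN convention above and should
  not be compared against values computed under a different one.
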