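---
title: "Modified SegNet networks for polyp segmentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modified SegNet networks for polyp segmentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypseg)
```

## The segmentation problem

Colonoscopy screening produces RGB frames in which polyps -- abnormal
tissue growths on the colon wall -- must be delineated pixel by pixel.
The two classes are heavily imbalanced (polyps typically occupy a small
minority of pixels), polyps vary widely in size, shape and contrast, and
the background mucosa is visually similar to polyp tissue.  `polypseg`
implements a family of encoder-decoder convolutional networks for this
task, together with the training protocol, the pixel-wise evaluation
suite, dataset handling and a procedural fixture generator, so that every
part of the system can be exercised on one CPU with no external data.

## Model family

The backbone is a SegNet: a VGG-19 convolutional encoder mirrored by a
decoder that restores resolution with *max-unpooling* -- each 2x2/stride-2
max-pooling layer records the argmax position of every window, and the
matching decoder stage scatters values back to exactly those positions,
zeros elsewhere.  This keeps upsampling parameter-free and preserves the
spatial detail that ordinary interpolation loses.  Every convolution is a
*block*: convolution (with bias), batch normalisation (trainable scale
and shift), then ReLU.

Three modifications are applied to the baseline:

1. **Skip connections.**  The pre-pool output of every encoder depth is
   merged into the matching decoder depth right after its unpooling
   stage.  The default merge is element-wise addition, which adds no
   parameters; channel concatenation is also implemented
   (`skip_merge_mode = "concat"`).
2. **5x5 convolution blocks.**  The two shallowest depths carry two extra
   5x5 blocks each, appended after the 3x3 blocks on the encoder side and
   prepended on the decoder side, mirroring the structure.  Wider kernels
   at high resolution stabilise shallow features against local noise.
3. **Dilated-convolution pyramid.**  At the encoder bottleneck, four 3x3
   convolution blocks with dilation factors 1, 6, 12 and 18 run in
   parallel on the same input; a 3x3 kernel at dilation $l$ covers
   $3 + 2(l-1)$ cells per axis, so the branches see receptive fields of
   3, 13, 25 and 37 cells at unchanged resolution.  Their outputs are
   concatenated and projected back to the bottleneck width by a final
   3x3 block.

Three depth variants share this structure and differ only in the encoder
channel plan (the decoder is always the exact mirror):

| variant    | encoder channels                  | layers | parameters |
|------------|-----------------------------------|--------|------------|
| `small`    | 64, 128, 256                      | 100    | 10.4M      |
| `proposed` | 64, 128, 256, 512, 512            | 154    | 51.5M      |
| `large`    | 64, 128, 256, 512, 512, 1024, 1024| 208    | 206.7M     |

Layer counts use the primitive-layer convention: the input layer, every
convolution, batch normalisation, ReLU, pooling, unpooling and merge
layer (including the pyramid concatenation), the softmax and the
pixel-classification output each count once.

### Calibrated pyramid widths

The one width the architecture does not pin down structurally is the
channel count of the pyramid branches.  We fix it per variant -- 200,
254 and 312 channels for `small`, `proposed` and `large` -- so that the
total trainable parameter count of each variant lands on its published
complexity budget (10.4M, 51.5M, 206.7M) at 0.1M rounding.  The budgets
are treated as the calibration oracle for this design freedom; no uniform
rule (branch width equal to, or a fixed fraction of, the bottleneck
width) reproduces all three budgets simultaneously, so the width is a
per-variant design constant of this package.  Parameter totals are
always computed twice -- by walking the built graph and by the closed
form $\sum_{\text{conv}} k^2 C_{in} C_{out} + C_{out} +
\sum_{\text{bn}} 2C$ -- and the two must agree.  Batch-norm running
statistics are not trainable and are not counted.

## Training protocol

`train_config()` encodes the optimisation protocol: stochastic gradient
descent with momentum 0.9, base learning rate 0.001, 100 epochs,
mini-batches of 4, and the learning rate multiplied by 0.3 after every
10 epochs:

```{r}
lr_schedule(c(1, 11, 21), train_config())
```

The loss is the 2-channel softmax cross-entropy averaged over pixels
(equivalently, binary cross-entropy on the polyp-probability channel).
No class weighting, weight decay or gradient clipping is applied.

**Batching.**  The default batcher streams shuffled samples continuously
across epoch boundaries, so a run takes exactly
$\lfloor n \cdot \text{epochs} / \text{batch} \rfloor$ gradient steps --
831 training images for 100 epochs at batch 4 give 20,775 iterations,
with the 3-image remainder of each pass rolling into the next.  A
conventional per-epoch batcher (partial final batch each epoch,
$\text{epochs} \cdot \lceil n/\text{batch} \rceil$ steps) is available
via `batcher = "per_epoch"`.

**Initialisation and determinism.**  Weights are He-initialised
(`sd = sqrt(2 / fan_in)`) from a user-supplied seed recorded in the
model; shuffling uses the training seed.  Two runs with identical seeds
produce identical loss traces.  A run aborts with a diagnostic if the
loss becomes non-finite.

## Evaluation metrics

From the pixel confusion counts (TP/FP/TN/FN, polyp = positive):
accuracy $(TP{+}TN)/N$; sensitivity $TP/(TP{+}FN)$; specificity
$TN/(TN{+}FP)$; precision $TP/(TP{+}FP)$; class IoU $TP/(TP{+}FP{+}FN)$
and $TN/(TN{+}FP{+}FN)$; mean IoU (their average); Dice
$2TP/(2TP{+}FP{+}FN)$; and F2, the $F_\beta$ measure at $\beta = 2$,
which weights recall above precision.  Two aggregations are provided:
`per_image_mean` (the default; the arithmetic mean of per-image metrics)
and `dataset_aggregate` (metrics of the pooled counts).  They genuinely
differ, which is why both are exposed.

**Zero denominators.**  An image with no polyp pixels makes sensitivity,
precision and polyp IoU 0/0.  We define such a ratio as 1 when the
complementary error count is also zero (the requirement holds vacuously:
nothing to find, nothing found) and 0 otherwise, and flag the report
`degenerate`.  This keeps per-image averaging total without hiding the
convention.

Per-image accuracies can be binned into the six standard reporting
ranges (90--100%, 80--89.99%, ..., 0--49.99%) with `bin_accuracies()`.

## Dataset handling

`load_dataset()` reads one or more collections of image/mask pairs
(PNG/TIFF, paired by filename stem; unpaired files are an error listing
the offending stems).  Masks binarise with the 8-bit rule value > 127 =>
polyp.  `split_dataset()` pools all records and tags a seeded random 70%
as training, the rest as testing -- disjoint by construction; the
`per_collection_counts` argument reproduces an exact published
allocation instead.  `standardize_sample()` resamples images bilinearly
and masks by nearest neighbour (then re-binarises) to a common
resolution, by default 288 x 384, the smallest native resolution among
the public polyp collections.  Inputs whose size is not divisible by
$2^{\text{depth}}$ are zero-padded internally and cropped back, so
predictions always match the input resolution.

## Synthetic fixtures

`generate_sample()` renders the features that drive segmentation
difficulty at a controllable level: a mucosa-toned background with
smoothed low-frequency texture, radial vignetting mimicking endoscope
illumination fall-off, small specular highlights, Gaussian pixel noise,
and one or more brighter elliptical "polyps" with random size,
eccentricity and orientation.  The mask is the exact union of the
ellipse interiors, rendered with 2x2 sub-pixel coverage and re-binarised
at 0.5, so mask and image are geometrically consistent by construction.
Defaults: 1--3 polyps per image with semi-major axes of 10--24% of the
short side, intensity contrast 0.30 over background, noise sd 0.03 --
values chosen once to give clearly learnable but non-trivial fixtures in
which polyps are a minority class, as in real frames.  Each sample is
fully determined by the generator seed and its index, so datasets
regenerate byte-identically and order-independently.

What the generator deliberately does not emulate: instrument and lumen
geometry, motion blur and interlacing artefacts, true polyp texture and
translucency, and annotation noise.  Tests that pass on these fixtures
therefore demonstrate that the implementation can represent and learn
the segmentation task, not that the trained weights transfer to real
colonoscopy data.

## Numerical choices

* The engine computes in single precision (the standard arithmetic for
  convolutional networks); convolutions are evaluated as im2col + BLAS
  GEMM.  Test comparisons against double-precision oracles use a 1e-6
  relative tolerance.
* Pooling ties break to the first occurrence in row-major window order,
  making argmax indices deterministic; the pool-then-unpool round trip
  is the identity on the non-negative maps that actually reach pooling
  (every pool follows a ReLU).
* Batch normalisation uses per-batch statistics during training (eps
  1e-5) and running averages (momentum 0.1) for inference; an untrained
  network falls back to batch statistics.
* Softmax is computed with the max-subtraction stabilisation; the loss
  floors probabilities at the double-precision minimum before taking
  logs.

## Problem sizes used by the test suite

The suite exercises everything on one CPU: unit and property tests use
feature maps up to 8 x 8 (1000-case property loops), networks at 16--64
pixel inputs, and the three full variants are built once each for the
parameter/layer accounting.  Backpropagation is verified against central
finite differences of the loss at representative tensors in every layer
role.  The learning check trains the `small` variant on 64 synthetic
64 x 64 frames under the reference protocol for 25 epochs -- the
training-accuracy plateau on this fixture is reached well inside that
horizon (the >95% bar is typically cleared before epoch 10), and because
the learning rate decays by 0.3 every 10 epochs, continuing further only
polishes a plateau at rates that have already shrunk by orders of
magnitude.  The full protocol remains available through `train_config()`
unchanged.

The learning check asserts the mean and median of the per-image Dice
coefficients on the training fixtures (the package's default per-image
aggregation).  Individual fixtures whose polyp is very small can stay
below the cohort level even when the overall segmentation is good:
per-image Dice correlates strongly with polyp area, and the hardest
small-polyp frames are exactly where encoder-decoder segmenters lose
objects -- the motivation for the dilated pyramid in the first place.
A per-image floor is therefore not asserted; the distribution is the
honest summary.

## Known limitations

* The published benchmark results on the three public colonoscopy
  collections require downloading those datasets and GPU-scale training;
  the package reproduces the architecture accounting, protocol
  arithmetic and metric machinery at desk scale instead.
* The trainer keeps the training set and per-layer im2col workspaces in
  memory; training the `proposed` variant at full 288 x 384 resolution
  is therefore a GPU-scale undertaking outside the test envelope.
* `large` (208 layers) needs inputs divisible by 128 after padding and
  roughly 2.5 GB of memory just to hold its weights during construction.
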