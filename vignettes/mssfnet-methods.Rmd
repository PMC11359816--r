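---
title: "Methods: spatial-spectral segmentation of floating raft aquaculture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-spectral segmentation of floating raft aquaculture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Floating raft aquaculture (FRA) — seaweed and shellfish grown on anchored
raft-and-rope grids in coastal waters — appears in Sentinel-2 surface
reflectance as regular dark strip blocks over brighter seawater: raft
reflectance is a fraction of the surrounding water's in every band.
Mapping FRA extent from imagery is a binary semantic-segmentation problem
complicated by thin structures (strips are often only 1–4 pixels wide at
10 m), spectrally similar confusers (suspended sediment, cloud, shadow,
tidal flats) and wide variation in block size and orientation.

This package implements a multiscale spatial–spectral fusion network for
that task, together with everything needed to train, evaluate and apply it:
dataset construction from rasters, a training loop, a metric suite, a
whole-raster predictor, and a seeded synthetic scene generator that makes
the entire pipeline verifiable on a desktop without any satellite downloads.

## Model

The network is a UNet-style encoder–decoder. The encoder has the shape of
ResNet18 — a 7×7 stride-2 convolution, batch normalisation, ReLU and a 3×3
stride-2 max-pool, followed by four stages of two blocks — but every
residual block is replaced by a **spatial–spectral feature extraction block
(SSFEB)**, and a **multiscale spatial attention block (MSAB)** sits on the
1/32-resolution bottleneck map.

### SSFEB

Each SSFEB fuses three terms residually,

\[ F_G(x) = K_{spa}(x) + K_{spe}(x) + x, \]

so a block with zeroed branch projections is exactly the identity (a
property the tests assert bit-for-bit).

The *spectral branch* `K_spe` permutes the (batch, channel, height, width)
map so that the original width axis becomes the grouping axis and depthwise
kernels slide over the (height × original-channel) plane. The permuted map
is split into three equal groups along the grouping axis; each group gets
its own depthwise kernel — 3×3 for local structure, 1×11 spanning eleven
spectral channels, and 11×1 spanning eleven rows — so the long kernels
extract long-range spectral correlations, which is the point of the
permutation. The groups are re-concatenated, batch-normalised, passed
through a two-layer 1×1 perceptron (GeLU between, expansion 4), cropped of
any grouping-axis padding, and permuted back. Two consequences worth
noting:

* the number of depthwise filters equals the feature-map width at that
  stage, so a built network accepts exactly one tile size; the forward pass
  rejects other widths with an explicit error;
* when the width is not divisible by three the grouping axis is zero-padded
  up to the next multiple, the padded positions are recorded, and they are
  cropped again before the inverse permutation, keeping the concatenation
  well defined at every stage.

The *spatial branch* `K_spa` is a 1×1 reduction to `C/r` channels (r = 4 by
default), a depthwise 3×3, and a 1×1 restoration — a separable bottleneck
that keeps the parameter count low.

### MSAB

The attention block projects the input with a 1×1 convolution to stacked
query/key/value maps (3C channels), aggregates them with one depthwise
convolution per scale (3×3 and 5×5), flattens each aggregated map to
N = h·w tokens, and applies softmax-free **ReLU linear attention** per
scale:

\[ A_i = \frac{q'_i \, (K'^\top V)}{q'_i\,(K'^\top \mathbf{1}) + \varepsilon},
   \qquad q' = \mathrm{ReLU}(q),\; K' = \mathrm{ReLU}(K), \]

computed in the O(N·d²) association order (keys against values first).
The printed form of the association omits the denominator; the normaliser
is included by default because the unnormalised form is scale-divergent and
untrainable, and a `normalized = FALSE` switch reproduces the raw
association for reference. With a single token the normaliser makes the
output equal `v` exactly; rectified-away queries give exactly zero. The
per-scale outputs are concatenated over channels, projected 2C→C by a 1×1
convolution, and added to the input; a BatchNorm + GeLU MLP with a second
residual closes the block, so zeroing the two projections again yields an
exact identity.

Attention is evaluated in double precision throughout (R numeric), with
ε = 1e-6 guarding the denominator.

### Decoder and head

The decoder mirrors UNet: four levels of 2× bilinear upsampling (chosen
over transposed convolution to avoid checkerboard artifacts), concatenation
with the matching encoder skip (stage 3, stage 2, stage 1, stem), and two
3×3 convolution + BatchNorm + ReLU layers. Because the encoder performs
five 2× reductions, a final 2× bilinear upsample precedes the 1×1
convolution and sigmoid that produce the full-resolution probability map.
Threshold ties (p = 0.5) classify as positive.

Initialisation is He-uniform for convolution weights, zeros for biases,
ones/zeros for normalisation parameters, all drawn deterministically from a
user seed. The forward and backward passes of every layer are implemented
in this package (im2col + GEMM convolution kernels in C++); all backward
passes are verified against central-difference differentiation in the test
suite.

## Losses and metrics

Training minimises the equally weighted sum of binary cross-entropy
(predictions clamped at 1e-7) and Dice loss with smooth term s = 1 (s is a
configuration field; the worked-example tests set s = 0 where hand values
assume it). Evaluation pools confusion counts over the whole tile set
(micro-averaging, matching single dataset-level reporting) and derives
precision, recall, F1, IoU, overall accuracy OA, expected accuracy EA and
Cohen's kappa; the identity F1 = 2·IoU/(1+IoU) holds to 1e-12 and is
asserted on a thousand random count vectors. Degenerate denominators
(TP+FP = 0, TP+FN = 0, EA = 1) define the affected quantity as 0 and set a
flag, so downstream code never meets NaN. Counts are held as doubles: the
EA product exceeds 32-bit integer range on pooled evaluation sets.

## Dataset construction

* **Resampling** of 20 m bands to 10 m uses bilinear interpolation with the
  pixel-centre (half-pixel) convention standard in raster processing.
* **Normalisation** divides L2A digital numbers by 10 000 and clips to
  [0, 1].
* **Tiling** slides a half-open window (512 px, step 256 by default) in
  0-based (row, col) coordinates, adding a window snapped flush to the far
  edge when the step grid overruns, so every pixel is covered — required
  for whole-raster inference.
* **Filtering** drops zero-FRA tiles unless they intersect a user-supplied
  keep region (rasterised land/tidal-flat polygons) or are retained as
  seeded-probability negatives; every decision is logged.
* **Augmentation** emits the original, horizontal flip, vertical flip and
  main-diagonal transpose (anti-diagonal behind a flag), an exact 4×
  expansion applied identically to image and mask.
* **Splitting** assigns floor(0.2 n) tiles to test and floor(0.1 n) to
  validation with the remainder to training — the only rounding convention
  that produces 7051/2014/1007 from 10 072 — by a seeded shuffle after
  augmentation; variants of one scene can therefore straddle splits, which
  users evaluating generalisation should keep in mind.
* **Stitching** of tile predictions takes the per-pixel mean over
  overlapping tiles and errors on uncovered pixels.

Rasters travel as multi-page 32-bit float TIFFs in the fixed band order
B2, B3, B4, B5, B6, B7, B8, B8A, B11, B12, georeferenced by a plain-text
worldfile (.tfw) and CRS sidecar; masks are PNGs; every tile directory
carries a CSV manifest.

## Training loop

Adam (β = 0.9/0.999, no weight decay) with per-step cosine annealing
`lr(t) = lr_min + (lr0 − lr_min)(1 + cos(π t/T))/2` over the whole run, no
warm restarts. Full-scale defaults follow the published recipe: lr0 = 1e-4
to 0, batch 8, 50 epochs, online random scaling (0.75–1.25), shear warping
(≤5°), flips (p = 0.5 each) and uniform contrast gain (0.8–1.2) on top of
the offline 4× mirror expansion. Checkpoints store parameters, optimizer
moments, epoch/step counters and the RNG state, making training exactly
resumable; the best checkpoint is selected by validation IoU. With a fixed
seed, two runs produce bit-identical logs.

## Synthetic scenes

The generator emulates the phenomenology the network is built for: blocks
of parallel dark strips (width 1–4 px, seeded orientation, spacing and
grid shape) rendered without anti-aliasing at pixel centres, so the mask is
the exact rasterised strip set. Water reflectance uses a plausible winter
coastal spectrum; per-pixel noise is drawn once and shared across bands
with correlation 0.8, mimicking correlated reflectance; raft pixels take
`water × contrast` per band (contrast in (0,1), so rafts are strictly
darker in expectation in every band — asserted per band on generated
scenes). Distractors — suspended-sediment blobs brighter in the visible
bands, cloud patches bright in all bands, and a land margin with a
soil/vegetation spectrum — create the documented confusion modes and are
always labelled background. Scenes regenerate bit-identically from their
spec (including its seed), and a dataset's manifest records every spec as
JSON for replay.

What the generator does **not** model: radiative transfer, sun glint,
adjacency effects, sensor PSF/MTF mixing at strip edges, tides, or the
within-scene spatial autocorrelation of real water masses. Passing the
synthetic end-to-end test therefore demonstrates that the architecture,
gradients, training loop and evaluation harness work — not that the model
reaches any particular accuracy on real Sentinel-2 scenes.

## Desk-scale problem sizes and the end-to-end run

All tests run on a single CPU. The end-to-end check trains a tiny model
(64 px tiles, width multiplier 0.125, ~132 k parameters) for 20 epochs on
64 synthetic 64×64 tiles, selects the best-validation-IoU checkpoint over
8 validation tiles, and evaluates on 16 held-out tiles. For this ~640-step
schedule the learning rate is scale-adjusted to lr0 = 2e-2 (cosine to 0)
with batch 2 and the offline/online augmentation disabled — a short-schedule
setting chosen by the usual scaling reasoning (few steps, tiny width, small
batch), not the full-scale recipe, which remains the configuration default.
Held-out IoU ≥ 0.70 is reached for at least two of three seeds; scenes
dominated by 1-px-wide strips at oblique orientations are the typical
failure mode of the remaining seed, as sub-pixel strips rasterised without
anti-aliasing are genuinely ambiguous at this training budget.

## Reproducing the published-scale experiment

The full-scale configuration (`network_config()` defaults: 512 px tiles,
widths 64–512, 10 bands; `train_config()` defaults) corresponds to the
published training recipe on the CHN-YE7-FRA dataset (2518 512×512
Sentinel-2 tile pairs, mirrored to 10 072 and split 7051/2014/1007). That
experiment needs the released dataset and accelerator-scale compute and is
out of scope for this package's CPU implementation; the CLI (`exec/mssfnet
make-tiles / split / train / eval / predict`) exposes the identical
pipeline for users who have both.

## Numerical choices and limitations

* BatchNorm uses biased batch variance for normalisation, unbiased updates
  of the running variance, momentum 0.1, ε = 1e-5.
* GeLU is exact (`x·Φ(x)`), not the tanh approximation.
* Bilinear upsampling uses the half-pixel convention with edge clamping;
  constants are preserved exactly.
* The split of the permuted spectral map assumes equal thirds, and
  BatchNorm in the spectral branch runs in the permuted layout,
  immediately after the concatenation it normalises.
* Single-head attention per scale; no identity (scale-1) branch.
* The compiled convolution is im2col + GEMM per (batch, group); depthwise
  convolutions are the groups = channels case.
* Everything is CPU double precision; there is no GPU path, no mixed
  precision, and no distributed training.
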