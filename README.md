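# mssfnet

Semantic segmentation of offshore **floating raft aquaculture (FRA)** in
10-band Sentinel-2 surface-reflectance imagery. Raft-and-rope culture grids
appear as regular dark strip blocks over brighter seawater; this package
extracts them pixel-by-pixel with a multiscale spatial–spectral fusion
network, and ships the complete surrounding pipeline: dataset construction
from rasters, training, evaluation, whole-raster prediction, a synthetic
scene generator for desk-scale verification, and a command-line interface.

## The model

An encoder–decoder on the UNet pattern:

* **Encoder** — ResNet18-shaped (7×7/2 conv, BN, ReLU, 3×3/2 max-pool, four
  stages of two blocks), with every residual block replaced by a
  **spatial–spectral feature extraction block (SSFEB)**:

      F_G(x) = K_spa(x) + K_spe(x) + x

  The spectral branch `K_spe` permutes the feature map so depthwise kernels
  (3×3, 1×11, 11×1) slide over the (height × channel) plane — the 1×11
  kernel spans eleven spectral channels — followed by BatchNorm and a GeLU
  perceptron; the spatial branch `K_spa` is a 1×1 → depthwise 3×3 → 1×1
  bottleneck.

* **Bottleneck** — a **multiscale spatial attention block (MSAB)**: 1×1 QKV
  projection, depthwise aggregation at scales {3, 5}, and softmax-free ReLU
  linear attention per scale,

      A_i = q'_i (K'ᵀ V) / (q'_i (K'ᵀ 1) + ε),   q' = ReLU(q), K' = ReLU(K),

  computed in O(N·d²), then a 1×1 projection + residual and a BatchNorm +
  GeLU MLP + residual.

* **Decoder** — four levels of bilinear 2× upsampling with encoder skips and
  paired 3×3 conv+BN+ReLU, then a 1×1 convolution + sigmoid probability
  head (threshold 0.5, ties positive).

Training minimises equally weighted binary cross-entropy + Dice loss with
Adam and cosine annealing. Evaluation pools pixel confusion counts and
reports precision, recall, F1, IoU, overall/expected accuracy and Cohen's
kappa (F1 ≡ 2·IoU/(1+IoU)).

All forward *and* backward passes are implemented in the package (im2col +
GEMM convolution kernels in C++ via Rcpp/RcppArmadillo); no deep-learning
framework is required. Every backward pass is checked against numerical
differentiation in the test suite.

## Worked example

Train a tiny model on seeded synthetic raft scenes and evaluate held-out
tiles (about two minutes on one CPU):

```r
library(mssfnet)

scenes <- generate_dataset(88, seed = 1)           # 64 train / 8 val / 16 test
tiles  <- lapply(scenes, function(sc) list(image = sc$stack$data, mask = sc$mask))

model <- build_model(network_config(tile_size = 64L, width_multiplier = 0.125),
                     seed = 1)
count_parameters(model)
#> [1] 131937

cfg <- train_config(lr0 = 2e-2, epochs = 20L, batch_size = 2L, seed = 1,
                    augment = FALSE, checkpoint_dir = "run1")
res  <- train_model(model, tiles[1:64], val_tiles = tiles[65:72], cfg = cfg)
best <- load_checkpoint(file.path("run1", "best.ckpt"))$model

ev <- evaluate_model(best, tiles[73:88])
unlist(ev$metrics[c("F1", "IoU", "Kappa")])
#>        F1       IoU     Kappa
#> 0.8681342 0.7669940 0.8525500
```

`F1`/`IoU`/`Kappa` are pooled pixel metrics over the 16 held-out scenes: the
model recovers ~77% of the raft/background union despite strips only 1–4
pixels wide. Whole rasters are predicted with overlap-averaged stitching:

```r
sc <- generate_scene(scene_spec(size = c(96L, 96L), seed = 7))
pr <- predict_raster(best, sc$stack, tile_size = 64L, step = 32L)
mean(pr$mask)        # FRA cover fraction of the scene
```

## Command line

```sh
exec/mssfnet synth      --n 16 --size 64 --out scenes/ --seed 1
exec/mssfnet make-tiles --image stack.tif --mask labels.png --out tiles/ --augment
exec/mssfnet split      --tiles tiles/ --seed 1
exec/mssfnet train      --tiles tiles/ --out run/ --epochs 50 --batch-size 8 --lr 1e-4
exec/mssfnet eval       --tiles tiles/ --checkpoint run/best.ckpt
exec/mssfnet predict    --image bay.tif --checkpoint run/best.ckpt --out bay_pred
```

Rasters are multi-page float TIFFs (band order B2,B3,B4,B5,B6,B7,B8,B8A,
B11,B12) with plain-text worldfile/CRS sidecars; masks are PNGs; tile
directories carry CSV manifests.

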