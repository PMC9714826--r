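# strokeloc

Detection and localization of acute ischemic stroke infarcts on
non-contrast CT (ncCT), trained against perfusion-derived label maps.

Early infarcts are subtly hypodense on ncCT — a few Hounsfield Units (HU)
below the surrounding tissue, inside several HU of noise — which is why
first-line CT reads miss so many of them. CT perfusion (CTp) shows the
lesion (infarct core and hypoperfused tissue) but needs contrast and
processing software. `strokeloc` implements an end-to-end pipeline that
learns the ncCT appearance of the infarct from paired CTp labels:

* **Preprocessing** — skull stripping (bone/air HU thresholds, largest
  4-connected component, hole filling), rigid alignment of the CTp frame
  to the CT grid by minimizing the symmetric-difference area of the two
  brain-mask convex hulls over (scale, θ, tx, ty), and nearest-neighbour
  label transfer.
* **Feature maps** — four per-pixel maps: three seeded miniature
  encoder–decoder networks with dilated convolutions (F1–F3), and F4 from
  a pixel-wise network over the hand-crafted vector

  `P(i,j) = [C_max, C_μ, C_x̃ (own cell); C_max, C_μ, C_x̃ (contralateral
  cell); K_max, K_μ, K_x̃, K_bilat (sliding windows 8/16/32); G_max, G_μ,
  G_x̃]`

  where C compares 16×16 cells mirrored across the brain-mask midline, K
  are window statistics plus a bilateral-filter value, and G are global
  in-mask statistics.
* **Ensemble** — blocks stacking `[F1, F2, F3, F4, mask]` for 1/3/5
  neighbouring slices, fused by a two-layer CNN (64 kernels 3×3 + ReLU,
  mask-gated; 3 kernels 1×1 + ReLU; softmax). The infarct channel is the
  probability map `L`, thresholded at 0.5.
* **Postprocessing** — keep the hemisphere with the largest connected
  detection, zero the other side.
* **Evaluation** — 32×32-cell majority-rule subsampling with precision =
  TP/(TP+FP), recall = TP/(TP+FN), F1, accuracy over in-mask cells, and
  pixel IoU = |A∩B|/|A∪B|, in a leave-one-out harness.

A seeded phantom generator (elliptical brain in a skull ring, one-sided
subtle hypodense lesion, misaligned perfusion-style label map at a
different aspect ratio) makes the whole pipeline runnable and testable
without clinical data. See the methods vignette
(`vignettes/strokeloc-methods.Rmd`) for the models, parameter choices and
limitations.

## Worked example

Train on 5 phantoms, predict a held-out case:

```r
library(strokeloc)

ds    <- generate_dataset(6, "medium", master_seed = 42)
cfg   <- pipeline_config(block_size = 3)
cases <- lapply(ds$cases, prepare_case, config = cfg)

fit  <- train_pipeline(cases[1:5], cfg, seed = 1)
pred <- predict_case(fit, cases[[6]])
evaluate_case(pred$pred, cases[[6]]$truth, cases[[6]]$mask)[
  c("iou_pixel", "precision_pixel", "recall_pixel")]
```

```
$iou_pixel
[1] 0.7701711

$precision_pixel
[1] 0.7701711

$recall_pixel
[1] 1
```

The held-out lesion is recovered with pixel IoU 0.77: the detection
covers the entire true lesion (recall 1) and 77% of the detected pixels
are truly lesion (precision). `pred$side` reports which hemisphere the
postprocessing kept, and `pred$L` holds the raw probability map.

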