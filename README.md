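# fissureseg

Per-pixel segmentation of tongue fissures — the thin, branching, darker
grooves whose pattern is a diagnostic sign in traditional Chinese
medicine — for people building or studying computer-aided tongue-diagnosis
pipelines. The package implements an improved U-Net whose encoder is an
Inception-style backbone and whose skip pathways pass through large-kernel
**Global Convolutional Network (GCN)** modules and **Boundary Refinement
(BR)** blocks, together with a synthetic fissured-tongue generator with
pixel-exact ground truth, flip/rotation augmentation, a fully seeded CPU
training engine, confusion-matrix metrics, an ablation harness, and an
end-to-end experiment pipeline with a command-line interface.

## The model in brief

Semantic segmentation needs two things at once: *classification* (a large
receptive field connecting each pixel to enough context) and
*localization* (scores aligned to pixel coordinates). A GCN module serves
both by approximating a dense k×k convolution with the sum of two
separable branches,

    GCN_k(x) = conv_{1×k}(conv_{k×1}(x)) + conv_{k×1}(conv_{1×k}(x)),

mapping encoder features straight to per-class score maps with parameters
growing linearly rather than quadratically in k (at k = 7, 64→2 channels:
1,848 weights vs 6,272 for the dense kernel). A BR block then refines
boundaries residually, `x + conv(relu(conv(x)))`, zero-initialized so it
starts as the identity. The decoder upsamples the deepest score map ×2 at
a time, adds the next-shallower GCN output, applies BR, and repeats until
input resolution. Per-class IoU and their mean (MIoU) over one
dataset-level confusion matrix are the headline metrics:

    IoU_c = TP_c / (TP_c + FP_c + FN_c),   MIoU = mean_c IoU_c.

A depthwise-separable GCN variant, VGG / SE-ResNet / plain-U-Net encoder
ablations, and a classic U-Net baseline are included.

## Worked example

Train the improved U-Net from scratch on the synthetic benchmark (64
training images at 64×64, desk-scale profile) and evaluate on 16 held-out
images — about half a minute on one CPU:

```r
library(fissureseg)

params  <- synthetic_params(image_size = c(64L, 64L))
samples <- generate_dataset(params, 80, seed = 42)
samples[[1]]
#> <fissure_sample> sample_0001: 64x64, 372 fissure pixels (9.08%)

sp      <- split_dataset(seq_along(samples), 0.8, seed = 42)
profile <- desk_profile(epochs = 20)
model   <- build_improved_unet(profile$model, seed = 42)
model
#> <fissure_model> 155 nodes, 82,110 parameters
#>   encoder: googlenet + GCN(k=7, dense) + BR, 2 classes

fit    <- train_model(model, samples[sp$train_ids], NULL, profile$train)
report <- evaluate(fit$model, samples[sp$held_out_ids])
report
#> <metrics_report> 16 image(s)
#>   PA    0.9096
#>   MIoU  0.6431  (per class: 0.9043, 0.3819)
#>   loss  0.1817
```

PA is the fraction of correctly labeled pixels; the two per-class IoUs are
background and fissure; MIoU is their mean. For context, the trivial
all-background predictor reaches MIoU 0.4696 on the same split (its
background IoU is high because fissures are sparse, its fissure IoU is 0),
so the 0.64 here reflects genuine fissure learning. `predict(fit$model,
samples[[3]])` returns a binary mask, and `overlay()` blends it onto the
image for inspection.

Real annotation data flows in through `read_annotation()` (labelme-dialect
polygon JSON) and `rasterize()`, or `read_mask()` for label-mask PNGs;
`run_experiment("config.yaml")` drives the whole
generate → augment → split → train → evaluate → overlay workflow from one
YAML file, and `inst/cli/fissureseg.R` exposes
`generate|augment|train|eval|predict|compare|run` as shell commands.

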