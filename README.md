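# lwseg — lightweight encoder–decoder networks for rice seedling segmentation

`lwseg` segments rice seedlings in 5-band multispectral UAV imagery of
flooded paddies, as two pixel-wise binary tasks: **stand detection**
(individual seedling plants against the water background) and
**seedling-row extraction** (the connected bands linking plants along each
machine-transplanted line).  It is aimed at agronomists and remote-sensing
researchers who need seedling maps from low-altitude multispectral flights
but cannot afford heavyweight segmentation backbones — the models are small
enough to profile, train and run at desk scale.

The package implements two lightweight fully convolutional
encoder–decoder networks and everything around them:

* **LW-Segnet** — 4 encoders with (2, 1, 1, 5) convolutions and
  index-recording max pooling; 4 decoders with (5, 1, 1, 2) convolutions
  fed by sparse unpooling from the stored argmax indices;
* **LW-Unet** — symmetric 2-convolution stages, bilinear 2× upsampling and
  channel concatenation skips;
* the **LHA** module (lightweight hybrid attention): a 1-D-convolution
  channel gate, `sigmoid(conv1d(max_c) + conv1d(mean_c))`, and an additive
  spatial gate, `sigmoid(conv7x7(max_{hw} + mean_{hw}))`, both multiplied
  into the feature map;
* the **SSPDC** block (separable spatial pyramid dilated convolution):
  depthwise 3×3 convolutions at dilations 1/2/3 (receptive fields 3/5/7)
  fused by a 1×1 pointwise convolution, each followed by batch norm + ReLU;
* the focal-weighted binary cross-entropy objective
  `-(1/n) Σ [α(1-p)^γ y log p + (1-α) p^γ (1-y) log(1-p)]`
  (α = 0.25, γ = 2) with native backpropagation and Adam;
* pixel metrics (precision, recall, IoU, F1 = 2TP/(2TP+FP+FN), overall
  accuracy, mIoU), micro-averaged over tiles;
* an analytic profiler for parameter and FLOP counts, exact against the
  allocated weights;
* a raster pipeline (radiometric `L = gain·DN + bias`, 512×512 tiling,
  seeded 6:1:3 splits, flip/rotate/resample augmentation, TIFF/PNG tile
  I/O with a manifest);
* a procedural generator of synthetic paddy tiles (300 mm × 150 mm
  transplanting grid at 20 mm/px, three density regimes, water glint,
  paired stand/row ground truth) so the whole system is testable without
  field imagery.

No external deep-learning framework is used: forward passes, gradients and
the optimizer are implemented in R over BLAS, with small compiled kernels
for the convolution inner loops.

## Worked example

```r
library(lwseg)

# efficiency profile of the two calibrated architectures
print(lw_profile("lw_segnet", 512))
print(lw_profile("lw_unet", 512))
profile_compare(58.7, 32.1)   # % complexity increase of one profile over another

# simulate a small synthetic paddy dataset and split it 6:1:3
cfg <- field_sim_config(size = 64, noise_sd = 0.005, glint_rate = 0, seed = 21)
records <- make_dataset(cfg, 40, regime = "medium")
records <- assign_split(records,
                        split_dataset(vapply(records, `[[`, "", "id"), seed = 7))

# train a small LW-Unet on the stand task and evaluate the test partition
model <- lw_fit(records, architecture = "lw_unet", task = "stand",
                widths = c(4, 8, 12, 16), epochs = 25, batch_size = 8,
                lr = 1e-2, seed = 9)
print(model)
print(lw_evaluate(model, records, split = "test"))
```

Output (about two minutes on one CPU):

```
<model_profile> lw_segnet @ 512x512
  parameters: 11,013,005 (11.0 M)
  flops:      140,221,804,544 (140.2 GFLOPs)
<model_profile> lw_unet @ 512x512
  parameters: 10,604,965 (10.6 M)
  flops:      113,083,829,248 (113.1 GFLOPs)
[1] 82.9

<lwseg> lw_unet (stand task)  widths 4/8/12/16  10825 params
  trained 25 epochs (75 steps), final loss 0.00494, train IoU 0.959
  config 0000a530  seed 9
P 97.12%  R 98.43%  IoU 95.63%  F1 0.98
```

The profiles show the calibrated default width ladders landing on the
11.0 M / 10.6 M parameter budgets, with LW-Unet cheaper than LW-Segnet on
both axes (the vignette discusses why the analytic GFLOP totals at 512×512
are necessarily in the hundreds for networks of this size).  The metric row
is the pooled (micro-averaged) test-partition result of the small training
run: with the easy synthetic contrast the 10.8 k-parameter LW-Unet separates
seedlings from water almost perfectly.  `predict(model, tile)` returns
per-pixel foreground probabilities; `type = "mask"` thresholds at 0.5.

A thin command-line wrapper ships in `inst/cli/lwseg.R`
(`simulate` / `train` / `eval` / `predict` / `profile` subcommands over
YAML configs).

## Package layout

* `R/blocks.R`, `R/nn-ops.R`, `src/kernels.cpp` — attention, SSPDC,
  pooling/unpooling, bilinear upsampling, with hand-derived backward passes
  (finite-difference verified);
* `R/architectures.R`, `R/network.R` — declarative specs, the layer plan,
  profiler and forward/backward execution;
* `R/metrics.R` — losses and evaluation metrics;
* `R/datapipe.R`, `R/synthfield.R` — raster pipeline and synthetic
  generator;
* `R/fit.R`, `R/cli.R` — `lw_fit()` returning an `"lwseg"` model with
  `print`/`summary`/`predict`/`plot`/`coef` methods, evaluation,
  checkpoints, config-driven orchestration;
* `vignettes/lightweight-seedling-segmentation.Rmd` — the methods vignette
  (model, assumptions, calibration, numerical choices, limitations).
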