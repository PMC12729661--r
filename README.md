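# emaseg

Automated eye-muscle-area (EMA) measurement from B-mode ultrasound in R:
segmentation of the longissimus dorsi cross-section with a state-space
(selective-scan) encoder–decoder network, conversion of the segmented mask
into a calibrated physical area, and statistical agreement analysis of
automated against expert reference measurements.

EMA — the cross-sectional area of the longissimus dorsi between the 12th
and 13th ribs — is a key carcass-quality phenotype in meat-sheep breeding.
Measuring it in vivo from ultrasound is hard: B-mode images are
speckle-dominated, low-contrast, and muscle boundaries are blurred or
partially missing. `emaseg` implements a segmentation network designed for
exactly this regime, plus the downstream measurement pipeline:

* **Five-stage state-space encoder** — a 7×7 stride-2 convolutional stem
  (instance-normalized), then patch embedding/merging with visual
  state-space (VSS) blocks whose core is a four-direction selective 2-D
  scan (SS2D): `h_t = exp(Δ_t A) h_{t−1} + Δ_t B_t x_t`,
  `y_t = C_t h_t + D ⊙ x_t`, with input-dependent Δ, B, C. Channels run
  48 → 96 → 192 → 384 → 768 while resolution falls S/2 → S/32.
* **Edge-enhanced skips (MSEE)** — a dilated-convolution context path
  (rates 6/12/18) with transposed channel attention, summed with a Sobel
  edge path, replacing plain U-Net skip connections.
* **Pyramid-attention bottleneck (PARM)** — pyramid pooling (1/3/5/7
  grids) feeding channel-compressed, grouped non-local attention with a
  residual output.
* **Context-aggregation decoder (GCAD)** — pre-norm residual blocks around
  a hierarchical dilated depthwise aggregation with a multiplicative SiLU
  gate, on a 2×-upsampling ladder that fuses the enhanced skips.
* **Hybrid loss** — `L = L_Dice + L_BCE`, optimized with AdamW.
* **Measurement framework** — foreground pixel count × per-pixel area
  (device calibration, mm²/px) gives the EMA; agreement against reference
  areas is quantified by MAE, MAPE, signed error mean (SEM) and Pearson r.

Because the underlying animal data are private, the package ships a
**synthetic phantom generator**: rotated superellipses with feathered,
partially broken bright rims in multiplicative Gamma speckle, with known
masks and pixel spacing — every stage of the pipeline is testable end to
end on a desktop CPU. The network itself runs on a small reverse-mode
autodiff core written for this package (R + C++ kernels), so training and
inference need no external deep-learning framework.

## Worked example

```r
library(emaseg)

## 1. simulate a small labelled dataset (8 phantoms, 128 x 128, 0.7 mm/px)
man <- generate_dataset(8, phantom_params(), "phantoms", seed = 123)
df  <- read_manifest(man)

## 2. train the reduced CPU profile (base width 16, one VSS block per stage)
cfg <- test_profile_config(batch_size = 4L, epochs = 60L, seed = 11L,
                           augment = default_augment_policy(
                             p_rotate = 0, p_scale = 0, p_elastic = 0,
                             p_brightness = 0, p_contrast = 0, p_noise = 0))
split <- list(train_ids = df$id, val_ids = character(0), test_ids = character(0))
fit <- train_model(cfg, df, split = split, max_steps = 100, verbose = TRUE)

## 3. predict, measure, compare
fr  <- load_frame(df$image_path[1], c(df$row_mm_per_px[1], df$col_mm_per_px[1]))
gt  <- load_mask(df$mask_path[1])
pr  <- predict_mask(fit$model, fr)
overlap_scores(confusion_counts(pr, gt))$dsc
#> [1] 0.9734816
measure_area(pr, calibration(0.7, 0.7))$area_mm2
#> [1] 861.91
measure_area(gt, calibration(0.7, 0.7))$area_mm2   # constructed ground truth
#> [1] 856.52
```

On this run the model reaches a train-set mean DSC of 0.975 (per-image IoU
0.93–0.96) after 100 optimizer steps, and the measured area of the
predicted mask (861.91 mm²) is within 0.7% of the phantom's constructed
ground-truth area (856.52 mm²). Feeding the reference masks themselves through the
measurement stage gives MAE = MAPE = SEM = 0 exactly — the pipeline adds
no numerical error of its own.

A command-line wrapper with `simulate`, `split`, `train`, `predict`,
`measure`, `evaluate` and `pipeline` subcommands is installed under
`exec/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "emaseg", package = "emaseg"))')" \
    simulate --n 8 --out phantoms --seed 1
```

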