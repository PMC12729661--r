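---
title: "Methods: state-space segmentation and calibrated eye-muscle-area measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-space segmentation and calibrated eye-muscle-area measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emaseg)
```

## The problem

The eye-muscle area (EMA) — the cross-section of the longissimus dorsi —
is measured in live sheep from B-mode ultrasound stills. The images are
speckle-dominated and low-contrast, with blurred and partially missing
muscle boundaries, so manual delineation is operator-dependent. `emaseg`
automates the chain *image → binary mask → pixel count → calibrated
physical area → agreement statistics*.

## The segmentation model

The network is a U-shaped encoder–decoder built from four components.

**Encoder.** A five-stage hierarchy: a 7×7, stride-2 convolutional stem
with 2-D instance normalization produces the first level (width
$C_1 = 48$ at full size); each later stage downsamples with a 2×2
convolutional patch embedding / merging and applies visual state-space
(VSS) blocks. A VSS block is a two-branch gated unit,

$$\mathrm{out} = x + W_o\!\left(\sigma(W_g \mathrm{LN}x) \odot
  \mathrm{LN}\,\mathrm{SS2D}(\sigma(\mathrm{DWConv}(W_i \mathrm{LN}x)))\right),$$

whose sequence core SS2D flattens the feature map in four orders
(row-major and column-major, forward and backward) and runs the selective
state-space recurrence
$h_t = e^{\Delta_t A} h_{t-1} + \Delta_t B_t x_t$,
$y_t = C_t h_t + D \odot x_t$ along each order, summing the four outputs.
$\Delta, B, C$ are input-dependent (a low-rank projection of the
sequence), which lets the state decay adapt to content — background
texture is forgotten quickly, muscle structure is carried far. Defaults
follow the small-vision-backbone convention: state dimension 16, channel
expansion 2, $\Delta$-rank $\lceil d/16 \rceil$. No positional embeddings
are used; the scan orders themselves carry position. Channels double per
stage (48…768) while resolution falls from $S/2$ to $S/32$.

**Edge-enhanced skips.** Each skip connection processes its feature map
along two paths. The context path sums a 1×1 convolution with three 3×3
dilated convolutions (rates 6, 12, 18), layer-normalizes, and applies
*transposed* (channel-to-channel) attention: with depthwise-separable
Q/K/V generators and reshaped $C \times HW$ matrices,
$\Lambda = \mathrm{softmax}(\tau\, \hat K \hat Q^{\top})$ (rows sum to 1;
$\tau$ a learnable temperature initialized at 1), and the path output is a
1×1 depthwise-separable projection of $\Lambda \hat V$. The edge path is
$e_s = \mathrm{DConv}_{1\times1}(x + \mathrm{DConv}_{3\times3}(
\mathrm{ReLU}(\mathrm{BN}(\mathrm{Sobel}(\mathrm{DConv}_{1\times1}x)))))$.
The module output is the element-wise sum of the two paths. The Sobel
magnitude is applied separably with the difference stage first and
replicate padding, so spatially constant inputs give *exactly* zero
response (borders included) — its backward pass clamps the square-root
derivative near zero instead of biasing the value with an epsilon.

**Pyramid-attention bottleneck.** The deepest map is pooled to 1×1, 3×3,
5×5 and 7×7 grids, each bilinearly upsampled and concatenated with the
input ($5C$ channels). Queries and keys are 1×1-compressed (width
$C' = C/4$) from the pooled stack, values from the raw input; attention is
non-local over all spatial position pairs (softmax over key positions),
processed in 4 channel groups for economy, then projected back to $C$ and
added to the input. When the bottleneck grid is smaller than a pooling
size (the reduced profile has a 4×4 bottleneck), that branch is dropped
rather than pooled "upward".

**Decoder.** Starting from the refined bottleneck, each stage upsamples 2×
by transposed convolution with channel halving, concatenates the
edge-enhanced skip, fuses with a 1×1 convolution to the stage width, and
applies a pre-norm residual block
$X_{S1} = X_A + \mathrm{Norm}(\mathrm{MCA}(X_A))$, $Y = X_{S1} +
\mathrm{MLP}(X_{S1})$ with $X_A = \mathrm{Norm}(x)$. MCA chains three 3×3
depthwise-separable convolutions with dilations 6, 4, 2 hierarchically
($F_1 = \mathrm{DWC}_6(X_A)$, $F_2 = \mathrm{DWC}_4(X_A + F_1)$,
$F_3 = \mathrm{DWC}_2(X_A + F_2)$), adds a stride-1 3×3 average-pooling
branch $F_4$ (replicate-padded, so constants pass through — a global pool
would make $F_1 + F_4$ shape-invalid), concatenates
$(X_A, F_2, F_3, F_1{+}F_4)$ to width $4C$ and gates it with the product
of two independently parameterized 1×1+SiLU paths. A final 2× expansion
and a 1×1 head produce single-channel logits; probabilities are the
logistic transform.

**Loss and training.** $L = L_{\mathrm{Dice}} + L_{\mathrm{BCE}}$,
unweighted. Dice uses a $10^{-5}$ smoothing term in numerator and
denominator so empty masks are defined; BCE clips probabilities at
$10^{-7}$. Full-size training uses AdamW, learning rate $10^{-4}$, weight
decay $5\times10^{-2}$, batch 12, 50 epochs, constant learning rate, no
early stopping. Augmentation (training only) applies random rotation
(±30°, p = 0.2), scaling (0.7–1.4, p = 0.2), elastic deformation
(p = 0.2) identically to frame and mask (mask nearest-resampled), and
brightness/contrast jitter and Gaussian noise to the frame alone.

## Numerical core

No deep-learning framework is assumed: the package carries its own
reverse-mode automatic differentiation over dense `(H, W, C)` arrays, with
C++ kernels for the convolutions (im2col + BLAS GEMM, computed directly in
R's column-major layout), the selective scan (with its analytic backward;
the per-step exponentials are hoisted into long contiguous loops so the
vectorized math library applies), and boundary distances. Every operator's
gradient is validated against central finite differences in the test
suite, and the scan against a plain-R sequential oracle. All arithmetic is
double precision. Weight initialization is fan-in uniform; the
$\Delta$-projection bias is initialized so $\mathrm{softplus}$ of it spans
$10^{-3}$–$10^{-1}$, and the state-decay matrix as $A = -\exp(A_{\log})$
with $A_{\log}$ the log row $1..N$ — the usual stable state-space
initialization.

## Synthetic phantoms: what they emulate and what they do not

Because the study's animal images are private, testing uses constructed
phantoms: a rotated superellipse (exponent 1.5–3, approximating the
bean-shaped muscle cross-section) with a configured area sampled from
356–1490 mm² (the span of adult sheep EMA), a darker interior, a bright
rim a few pixels wide with random angular breaks (probability 0.4),
optional bright streak artifacts, Gaussian boundary feathering (σ = 1 px),
and multiplicative unit-mean Gamma speckle (relative SD 0.35) followed by
a light blur — a standard desk-scale surrogate for fully developed
speckle. Background heterogeneity scales with the speckle strength, so
setting it to zero yields an exactly piecewise-constant image (several
tests rely on that limit). The default size is 128×128 at 0.7 mm/px
(a ~90 mm field of view that accommodates the whole area range);
512×512 is supported. The generator rasterizes on pixel centers and then
nudges the axes so the realized pixel area honours the configured range
(within ~0.5%).

Phantoms reproduce the *geometry and noise regime* of the task — low
contrast, broken bright boundaries, speckle, distractor streaks — but not
acoustic physics: no depth-dependent attenuation, no probe geometry, no
anatomical context (ribs, fascia), and one target per image. A model that
segments phantoms well has demonstrated capacity and a correct pipeline,
not clinical-grade performance; conclusions about real ultrasound
generalization require real data.

## Scaled-down study conditions

CPU suites use a named reduced profile: base width 16, one VSS block per
stage, 128×128 inputs, learning rate $10^{-3}$ (short small-sample runs
tolerate and need a larger step than the full-size schedule), batch 4. The
capability experiment trains this profile on eight phantoms (augmentation
off, as usual for an overfit diagnostic) for at most 100–150 optimizer
steps and evaluates on the training set; it reaches mean train DSC ≈ 0.97
with every per-image IoU above 0.93 on the pinned seed. This is a
deliberate overfit — it demonstrates that the architecture, gradients,
loss and optimizer work end to end at desk scale, nothing more.

## Design choices where the source was open

* *Attention axes.* The skip attention is channel-to-channel with softmax
  over the second channel axis and a learnable temperature; the bottleneck
  attention softmax runs over key positions. Neither axis nor temperature
  is forced by the published equations.
* *Pooled branches.* The bottleneck equation lists three pooled terms
  while the text names four pooling sizes; the default uses four branches
  + identity ($5C$ concat), configurable to three.
* *Residual placement.* The bottleneck residual is added outside the final
  1×1 convolution (the standard non-local form); the printed equation is
  typographically ambiguous.
* *Value embedding.* Bottleneck values are computed from the raw input
  (as printed), not the pooled stack.
* *"DConv".* Read as depthwise-separable convolution throughout, matching
  the pointwise∘depthwise factorization in the skip-attention equations
  and the decoder's explicit "depthwise separable" wording.
* *Decoder plumbing.* Upsampling is a 2×2 transposed convolution with
  channel halving (bilinear + 1×1 is available), skip fusion is
  concatenation + 1×1 (the U-Net convention), the block MLP expands 4×,
  norms are channel layer norms, and there is no deep supervision.
* *Stage depths.* The published depth list has five entries for four
  post-stem stages; the default places the blocks at the four
  downsampling stages, configurable.
* *Splits.* `floor(n·ratio)` per subset with the remainder to the training
  set — deterministic, and exact for the published 710-image 7:2:1 split
  (497/142/71).
* *Degenerate metrics.* Ratio metrics return 1 when the denominator is
  zero and the prediction is vacuously perfect, else 0. HD95 uses the
  pooled bidirectional surface-distance multiset with a type-7 quantile
  and errors (rather than returning infinity) on empty masks. Pearson r of
  two identical lists is returned as 1 with a degeneracy flag so the
  identity pipeline check is well defined; a constant non-identical list
  is an error.
* *Unit tags.* MAE/SEM are unit-tagged (px vs mm²) because the two are
  reported in different units in different places; the package never mixes
  them silently.

## Known limitations

* The full-size configuration has ≈ 29.9 M parameters, roughly half the
  ~61 M reported for the published model. The gap cannot be closed under
  the depthwise-separable reading of the decoder and skip modules and the
  stated compression widths; the undocumented widths of the original
  implementation evidently differ. Shapes, contracts and behaviour are
  unaffected; only the parameter budget differs.
* Training at the full 512² size is possible but slow on one CPU
  (~minutes per batch); the package is built to validate the method at
  reduced scale, not to reproduce GPU-scale benchmarks.
* HD95 is quadratic in boundary length (exact nearest-neighbour search);
  fine for single-organ masks, not for dense multi-object scenes.
* Checkpoints store plain R serializations of the weight arrays; they are
  not interchangeable with other frameworks' checkpoint formats, and
  loading pretrained backbone weights from elsewhere is out of scope.
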