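---
title: "SD-UNet: model, cost accounting and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SD-UNet: model, cost accounting and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sdunet)
```

# The model

SD-UNet is a lightweight variant of the U-Net encoder--decoder for 2-D
biomedical image segmentation. Three ideas are combined:

1. **Depthwise separable convolutions.** Every convolution except the
   very first is factorized into a depthwise stage (each input channel
   convolved with its own $k \times k$ filter, no cross-channel mixing)
   followed by a pointwise ($1 \times 1$) stage that mixes channels.
   A standard convolution costs $D_k^2 M N D_f^2$ multiplications over
   a $D_f \times D_f$ map with $M$ input and $N$ output channels; the
   factorized form costs $D_k^2 M D_f^2 + M N D_f^2$. Their ratio
   $D_k^2 N / (D_k^2 + N)$ approaches $D_k^2 = 9$ for $3 \times 3$
   kernels at large widths, which is where the roughly eightfold
   parameter and FLOP savings of the architecture come from
   (`cost_reduction_ratio(3, 512, 512)` $\approx 8.84$).

2. **Group normalization (GN).** Activations are normalized per example
   over spatial positions and channel groups, never across the batch,
   so micro-batches (the package default batch size is 2) behave the
   same as large ones. Default 32 groups; layers narrower than 32
   channels (or whose width is not divisible by the group count) fall
   back to one group per channel with a warning.

3. **Weight standardization (WS).** The depthwise $3 \times 3$ kernels
   are reparameterized at every forward pass:
   $\hat W = (W - \mu)/(\sigma + \varepsilon)$ per standardization
   group, where for a depthwise kernel the group is each channel's
   $k \times k$ filter. The optimizer steps on the raw $W$; gradients
   flow through the standardization (the backward rule is implemented
   analytically and verified against finite differences in the test
   suite). $\sigma$ is the *population* standard deviation and
   $\varepsilon$ (default $10^{-5}$) is added to $\sigma$ itself, not to
   $\sigma^2$; we note that some formulations use
   $\sqrt{\sigma^2 + \varepsilon}$ instead. A constant filter maps to an
   all-zero filter.

## Architecture reconstruction

The builders reproduce the published accounting exactly, and that
accounting was used as the arbiter wherever the prose description of
the block structure admits more than one reading:

* Topology: the classic four-pool U-Net skeleton -- five encoder levels
  with two convolutions per block and channel doubling
  $64 \to 1024$, four $2 \times 2$ max-poolings, skip concatenations at
  full pre-pool resolution, a decoder that upsamples by 2
  (parameter-free nearest neighbour) followed by a $2 \times 2$
  convolution, and a final $1 \times 1$ prediction convolution.
  Replacing every convolution except the first with its
  depthwise-separable factorization gives 3,901,441 kernel-and-bias
  parameters, plus 5,888 normalization affines: **3.9M**, with
  $2 \times$ kernel weights $= 7.79$M FLOPs under the accounting
  convention below. The unfactorized baseline has 31.0M parameters.
  A shallower three-pool reading of the block list lands near 2.9M and
  was therefore rejected. Consequence: input sides must be divisible by
  16; `sdunet_forward()` reflect-pads other sizes with a warning.
* Normalization placement: one GN (or BN, in the ablation variants) per
  block, after the block's second convolution, i.e.
  conv--ReLU--conv--norm--ReLU. Parameter counts are placement-invariant.
* Biases: standard and pointwise convolutions carry biases; the
  depthwise stage does not (it is immediately followed by the pointwise
  stage). Normalization layers carry per-channel scale and shift.
* WS applies to depthwise $3 \times 3$ kernels only -- not to the
  $2 \times 2$ decoder upconvolutions and not to pointwise kernels.
* Dropout (default rate 0.5) regularizes the two deepest encoder
  blocks, as in the U-Net lineage; the rate is configurable and the
  small-scale convergence tests set it to 0.
* Initialization: He-uniform kernels, zero biases, unit scales, all
  driven by one seed; two builds with equal seeds are bit-identical.

Six variants share this topology (`sdunet_variants()`): the proposed
model (separable + GN + WS), the plain U-Net, U-Net + GN, and the
separable model with BN and/or without WS. All separable variants have
identical parameter counts up to normalization-affine differences, and
toggling WS -- a reparameterization, not a parameter -- changes nothing
in the accounting.

## FLOP accounting conventions

`model_accounting()` reports two FLOP-like numbers, deliberately
labeled:

* `flops_2x_weights`: two operations (one multiply, one add) per
  convolution *kernel weight*, each kernel counted once -- i.e.
  $2 \times$ the kernel-weight count, excluding biases and
  normalization affines. This is the convention under which a
  31M-parameter U-Net is a "62M FLOP" model and the separable variant a
  "7.8M FLOP" one, and it is what the acceptance targets use.
* `mult_adds`: the standard per-output-pixel accounting, the two cost
  formulas above evaluated at each layer's own spatial size and summed.
  This is what a deployment engineer would call MACs; at
  $256 \times 256$ input it is three orders of magnitude larger than
  `flops_2x_weights`.

Model size on disk is reported as 4 bytes per parameter (weights-only,
float32). Published "size in memory" figures for some of these models
are consistent instead with weights plus two Adam moment buffers
($3\times$); we report the weights-only number and leave the
discrepancy documented rather than reproduced.

# Training engine

No deep-learning framework is used: forward and reverse passes are
written directly against dense `(batch, height, width, channel)`
arrays. Convolutions are evaluated as a sum over kernel taps of
spatially shifted slices times a channel-mixing matrix (nine matrix
products for a $3 \times 3$ kernel), which keeps everything inside
BLAS. The reverse pass is the exact adjoint; the test suite checks it
against central finite differences through the whole network, and the
layer outputs against independent nested-loop oracles.

Numerical choices worth knowing:

* "Same" zero padding, stride 1 everywhere; even ($2 \times 2$) kernels
  anchor top-left (pad bottom/right).
* Max-pooling routes the gradient to the first window position
  attaining the maximum on ties (measure-zero for continuous
  activations).
* Probabilities are clipped to $[10^{-7}, 1 - 10^{-7}]$ inside the
  losses; composed with the sigmoid head this yields the numerically
  stable $(p - y)/n$ logit gradient.
* Soft Dice uses a smoothing constant (default 1) in numerator and
  denominator, preventing $0/0$ on empty masks; the combined loss is
  `bce_weight * BCE - dice_weight * softDice` with default weights
  (1, 1). The EM-style binary task trains with BCE alone
  (`loss = "bce"`), the multi-class task with `dice_bce`, matching the
  learning-rate defaults of $10^{-4}$ and $10^{-5}$.
* Adam uses $\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\varepsilon = 10^{-8}$; moments are kept per tensor. Every source of
  randomness (initialization, shuffling, dropout, generators) is
  derived from explicit seeds, so runs are bit-reproducible on one
  machine -- the property the determinism tests assert.
* BN (ablation variants only) uses batch statistics in training and
  running averages (momentum 0.9) at evaluation; no further
  training-mode subtleties are modeled.

# Evaluation metrics

Pixel accuracy, IOU and Dice are computed from thresholded confusion
counts, with the empty-union convention (both sides empty scores 1,
exactly one side empty scores 0) and the algebraic identity
$\mathrm{Dice} = 2\,\mathrm{IOU}/(1 + \mathrm{IOU})$ property-tested on
random tables.

For boundary-map evaluation, `maximal_score_over_thresholds()`
binarizes the membrane probability map at each threshold in a sweep
(default 0.05--0.95, step 0.05), labels 4-connected components of the
non-membrane pixels as segments, and scores them against the reference
segmentation with:

* the foreground-restricted Rand F-score: harmonic mean (equal weights)
  of the pair-based merge and split probabilities, computed from the
  label contingency table restricted to reference-foreground pixels;
* the information-theoretic F-score: harmonic mean of $I(S;T)/H(S)$ and
  $I(S;T)/H(T)$ from the same table, with $0 \log 0 = 0$ and degenerate
  single-segment entropies scoring 1 only when both labelings are
  single-segment.

Restricting to reference foreground (membrane pixels carry label 0 and
are excluded) approximates the border-thinning of the public EM
challenge protocol; the challenge's official scripts are not reproduced
line by line, and its leaderboard numbers -- computed server-side on
hidden test labels -- are out of scope here. 4-connectivity is used
throughout because 8-connectivity leaks across 1-px diagonal membrane
gaps. Both scores are verified against explicit $O(n^2)$
pair-enumeration and direct-entropy oracles in the tests.

# Synthetic data

The generators exist so that every pipeline stage is testable without
downloads; they emulate statistical structure, not imaging physics.

* `generate_em_like()` builds a Voronoi tessellation from a
  minimum-separation point process (cell diameter $\approx 25$ px at
  the default `cell_density = 0.1`, preserved across image sizes), and
  renders walls 1--3 px wide (width jittered by a smooth random field,
  to exercise thinning behavior) as dark membrane pixels with mask
  value 0; interiors are bright with per-cell shading, correlated
  texture and white noise. The membrane-pixel fraction at defaults sits
  in the 0.05--0.35 band the tests assert. What it does *not* have:
  organelle interiors, membrane gaps/ambiguities, section artifacts --
  so passing scores here show algorithmic correctness, not EM-grade
  segmentation ability.
* `generate_brats_like()` renders four modality surrogates with
  distinct per-tissue contrast responses and a nested-ellipse label
  partition (background / edema / non-enhancing / enhancing, cores
  concentric inside the edema). A configurable fraction (default 0.25)
  of samples carries small tumors (under 2% of pixels) to exercise the
  small-lesion regime; large tumors draw area fractions uniform in
  6--14%. The implied expected class fractions are recorded in each
  sample's metadata and held to within 20% relative by a 200-sample
  calibration test. Not modeled: MRI bias fields, multi-institution
  intensity variation, real lesion morphology.
* `preprocess_sample()` center-crops (offsets
  $\lfloor(\mathrm{src}-\mathrm{crop})/2\rfloor$), resizes (bilinear
  image, nearest-neighbour mask) and standardizes each image to zero
  mean and unit population variance, mapping constant images to zeros.
* `augment_sample()` applies one jointly drawn flip/zoom/shift to image
  and mask, nearest-neighbour for labels (no fractional classes) and
  mirror reflection for out-of-bounds. Zoom 1 with zero shift is the
  exact identity and a flip is an exact involution -- both asserted.
  The zoom (0.9--1.1) and shift ($\pm 10\%$) defaults are conventional
  choices; they are configurable.

# Problem sizes and what the tests show

The suite runs entirely on one CPU. Graph-level tests use
$16$--$32$ px inputs with 4--8 base filters; the convergence sanity
check trains the real SD-UNet graph (base 8) on eight fixed synthetic
$64 \times 64$ EM-like samples for 200 Adam steps at learning rate
$10^{-3}$, batch 2, dropout 0, and requires training Dice above 0.95 --
an overfitting test that exercises every layer's forward and backward
pass end to end. The full-resolution ($256 \times 256$, base 64)
graphs are built and accounted, not trained. The published
full-dataset accuracy/Dice figures require GPU-scale training on the
external datasets and are deliberately not reproduced; the accounting
quantities (3.9M / 31M parameters, sub-8M FLOPs, $\ge 8\times$
factorization gain) are recomputed from scratch by
`scripts/acceptance.R`.

# Known limitations

* The claim that WS smooths and lowers the training-loss curve is a
  full-scale training-dynamics effect. In our desk-scale probes
  (48 px inputs, base 8, up to 150 steps, paired seeds) the WS variant
  consistently trailed its non-WS counterpart -- consistent with WS
  being a conditioning aid whose benefit emerges over thousands of
  iterations, not dozens. We therefore do not assert that property in
  the test suite, and treat WS's value at small scale as an open
  question rather than a verified benefit.
* Standardizing a 9-weight depthwise filter is aggressive: with so few
  weights per group, $\hat W$ has high variance and the effective scale
  of the depthwise stage is fixed at one, so the pointwise stage and GN
  affines must absorb all scale adaptation.
* The engine is plain R + BLAS; it is meant for correctness and
  desk-scale experiments, not throughput. Inference-time and
  memory-bandwidth behavior of the architecture is hardware-dependent
  and out of scope.
* `model_accounting()`'s two conventions bracket, but do not settle,
  what "FLOPs" should mean for a segmentation network; when comparing
  against other publications check which convention they use.

# Worked example

```{r example, eval = FALSE}
# build and account the full-size model
g <- build_sd_unet(model_config())
model_accounting(g)$totals_millions

# desk-scale training on synthetic membranes
data <- generate_em_like(8, 64, 64, seed = 11)
cfg <- model_config(input_height = 64, input_width = 64, base_filters = 8,
                    dropout_rate = 0)
fit <- train_sdunet(build_sd_unet(cfg), data,
                    train_config(learning_rate = 1e-3, epochs = 4,
                                 steps_per_epoch = 50, loss = "bce", seed = 9))
tail(fit$history, 1)
evaluate_model(fit, generate_em_like(4, 64, 64, seed = 99))
```
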