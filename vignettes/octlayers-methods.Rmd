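---
title: "Multi-scale attention segmentation of retinal layers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale attention segmentation of retinal layers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octlayers)
```

## The problem

Optical coherence tomography (OCT) B-scans resolve the retina into a stack
of tissue layers (NFL, GCL+IPL, INL, OPL, ONL, ELM+IS, OS, RPE) whose
thicknesses are early markers of ophthalmic disease.  `octlayers`
implements dense semantic segmentation of those layers: every pixel of a
grayscale B-scan receives one of `C` labels (eight layers plus background
in the standard healthy-eye layout; the class count is configurable for
layouts with an optic-disc or fluid class).

## The network

The model is an encoder–decoder convolutional network built around two
ideas: *keep full spatial resolution in the shallowest features*, and
*spend decoder capacity on attention rather than plain convolution*.

**Encoder.** A ConvNeXt-style backbone: blocks of 7×7 depthwise
convolution → layer normalization (over channels) → pointwise expansion to
4C with GELU → pointwise projection back to C, with a learnable per-channel
residual scale.  The stem is a 4×4 convolution with *stride 1*, so the
first stage operates at full resolution; stages 2–4 each halve the grid
(layer-norm + 2×2 stride-2 convolution).  The encoder therefore emits a
four-level pyramid F1′…F4′ at scales 1, 1/2, 1/4 and 1/8 — finer than
designs that downsample 4× in the stem and must upsample aggressively at
the end, losing boundary detail exactly where retinal layers are thinnest
(the fovea).

**Decoder.** Starting from F4′, three identical stages of:
2× upsampling (bilinear by default; a learned 2×2 stride-2 transposed
convolution is selectable) → channel concatenation with the
next-shallower encoder map → a *depth-efficient convolutional block
attention module* (DE-CBAM) that halves the channel count.  A final 1×1
convolution maps to the `C` class logits at input resolution.

**DE-CBAM.** The block keeps the published CBAM intact: a channel map
`Mc = σ(MLP(avgpool F) + MLP(maxpool F))` (shared one-hidden-layer MLP with
C/r units, outputs merged by summation) rescales channels, then a spatial
map `Ms = σ(f7×7[avgpool_c; maxpool_c])` rescales pixels.  Two consecutive
depthwise-separable convolutions (depthwise k×k + pointwise 1×1, each with
layer norm and GELU) are appended; the first pointwise stage halves the
channels and the second preserves them.  The ablation variant
(`attentionVariant = "CBAM"`) replaces the two separable convolutions with
a single 1×1 projection, so the harness can compare the two designs under
identical seeds; DE-CBAM always has strictly more parameters at equal
widths.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `stageWidths` | 24/48/96/192 | encoder channels per stage |
| `stageDepths` | 3/3/9/3 | ConvNeXt blocks per stage |
| `depthwiseKernel` | 7 px | encoder depthwise kernel |
| `camReduction` | 16 (clamped to C/2) | channel-attention bottleneck |
| `samKernel` | 7 px | spatial-attention kernel |
| `decoderKernel` | 3 px | DE-CBAM separable-conv kernel |
| `layerScale` | 1e-6 | residual scale init in encoder blocks |
| `learningRate` | 0.002 | Adam initial rate |
| `maxEpochs` | 300 | full training budget (no early stopping) |
| `steplrStep`, `steplrGamma` | 50, 0.5 | StepLR decay schedule |

The default stage layout follows the ConvNeXt depth pattern scaled down so
the whole network holds 1,940,947 trainable parameters — the ~1.9 M scale
of the design it implements; `countParameters()` reports the count for any
configuration and is verified against independent per-layer arithmetic in
the tests.  The exact depths at that parameter budget are not uniquely
determined, so both widths and depths are configuration fields rather than
constants.

Where the design space was genuinely open we chose once and exposed the
choice: the stem realizes its "no reduction" contract as a stride-1 4×4
convolution with (1,2) padding; DE-CBAM's halving happens in the first
pointwise stage; decoder separable convolutions use 3×3 depthwise kernels
(the customary separable-conv size, and far cheaper than 7×7 at full
resolution); each separable convolution is followed by normalization and
GELU (both toggleable in principle via the block internals); upsampling is
bilinear by default because it is parameter-free and avoids checkerboard
artifacts.  Weight initialization is fan-in-scaled ("He") by default —
with small CPU-scale models a fixed small-variance init plus the 1e-6
layer scale leaves the early training signal too weak to be useful; the
full-size default keeps `layerScale = 1e-6`, while the compact study
configuration uses 0.1.

## Training protocol

Per-pixel cross-entropy, Adam, and a StepLR schedule
(`lr0 · gamma^floor((epoch−1)/step)`).  Training always runs its full
epoch budget; after every epoch the mean foreground Dice on the validation
split is logged and the best-scoring weights are the ones kept ("best on
validation" selection — the selection metric is not named more precisely
by the protocol, so mean foreground Dice, the quantity reported
throughout, is used).  Augmentation (horizontal flip, rotation, Gaussian
blur, multiplicative contrast) applies to training samples only; the
geometric part transforms image and mask with one shared map, the mask by
nearest neighbour with exposed corners filled with background.  "Blur"
augmentation is implemented as Gaussian blur of the image; an additive
noise reading of the protocol is possible but was not adopted.  A single
master seed derives every RNG stream (weight init, shuffling, augmentation,
folds), so runs replay exactly.  `crossValidate()` builds k folds whose
validation sizes differ by at most one (126 ids, k = 4 → 32/32/31/31) and
reports per-class Dice both as mean ± sd across folds and per image, since
either aggregation may be wanted in a "value ± spread" table.

## Evaluation

From one-vs-rest confusion counts per class: `Dice = 2TP/(2TP+FP+FN)`,
`IoU = TP/(TP+FP+FN)`, micro accuracy `Acc = ΣTP / pixels`, and mean
per-class pixel accuracy `mPA = mean TP/(TP+FN)`.  The mIoU mean includes
the background class; classes absent from both masks are excluded from the
mIoU/mPA means.  A literal alternative for mPA — the mean of
`TP/(TP+TN+FP+FN)`, which approximates `Acc/C` rather than any per-class
accuracy — is available behind `formula = "as-printed"` for auditability,
but the conventional form is the default because only it can produce
per-class accuracies on the usual ~99 % scale.  Method comparison uses the
two-sided Wilcoxon rank-sum test on per-image scores: the exact
permutation distribution of the rank sum (midranks, so ties are exact) for
group sizes up to 25, and the normal approximation with tie and continuity
correction beyond; identical pooled samples return p = 1 with a warning.
Per-image disagreement maps (`errorMap()`) render the spatial error
distribution.

## Interpretation

`normalizeScores()` translates each pixel's m raw class values so the
minimum is strictly positive (shift −min + ε with ε set to 1e-6 of the
per-pixel value range; values already positive are left alone) and divides
by the sum — this makes the entropy well defined whether the inputs are
softmax outputs or raw logits, which is why the shift exists at all.
`entropyMap()` is the Shannon entropy `−Σ p log p` per pixel (natural log
by default, base 2 selectable), bounded by `log m`, zero exactly for
degenerate distributions.  `activationHeatmap()` adapts gradient-weighted
class activation mapping to segmentation: the class score is the sum of
that class's logits over pixels predicted as the class, channel weights
are spatially averaged gradients at the tapped layer (`de_cbam1..3` or the
output convolution), and the heatmap is the rectified weighted activation
sum, min–max scaled and bilinearly upsampled to image size.  The object
also carries the map at the tap's native resolution, because upsampling
low-passes the early layers' edge-like structure that makes the
shallow-vs-deep comparison interesting.  This is a standard Grad-CAM
adaptation; no claim is made that it matches any particular author
variant.

## The phantom generator

Real annotated B-scans cannot ship with the package, so every stage is
exercised on synthetic phantoms with pixel-exact masks.
`sampleBoundaries()` draws `nLayers + 1` non-crossing curves by cumulative
thickness stacking: each band thickness undulates around its mean as a sum
of three random-phase sinusoids bounded by `boundaryAmplitude`, and a
centred Gaussian foveal pit displaces the inner boundaries downward with
linearly decreasing weight (clamped bottom-up so ordering is preserved) —
inner layers thin at the fovea as they do anatomically.  `renderBScan()`
labels pixel centres by half-open band intervals, composites per-layer
reflectances (bright NFL/RPE, dark ONL) and applies multiplicative speckle
`I·(1 + s·N(0,1))`, clipped to [0,1].

The full-frame defaults emulate a healthy fovea-centred 500×750 scan; the
per-layer thicknesses keep the anatomically reported ordering (GCL+IPL,
ONL, ELM+IS thick; OS, NFL thin) and their sum is calibrated so the
rendered foreground fraction is 14.8 % — matching the average annotated
fraction of the dataset the format emulates (14.82 %), the only
composition statistic available for calibration.  `cropPhantomConfig()`
instead emulates a macular crop where bands fill most of a small frame:
the CPU-scale study uses 64×96 crops with eight 5-px bands and speckle
0.10.

What phantoms do *not* model: physically realistic OCT speckle statistics
(the noise is i.i.d. multiplicative, not interference speckle), A-scan
acquisition artefacts, vessels and shadows, pathology (fluid, drusen), or
annotation noise.  Passing the phantom study therefore shows the
implementation learns and evaluates correctly end to end — not that the
architecture attains clinical-grade accuracy, which requires the real
annotated datasets and full-scale training.

## Study sizes and numerical choices

The built-in study trains the compact configuration (widths 8/16/32/64,
one block per stage, layer scale 0.1, batch 1, flip + contrast
augmentation, 12 epochs) on 30 phantoms split 18/6/6 — sizes chosen so a
complete run takes a few minutes on one CPU core while leaving a wide
margin over its Dice ≥ 0.85 sanity bar (typical held-out mean Dice ≈
0.99 against ≈ 0.05 untrained).  Other numerics: layer-norm ε = 1e-6;
softmax and cross-entropy use max-shifted log-sum-exp; bilinear
upsampling aligns half-pixel centres with edge clamping; argmax ties
resolve to the lowest class index; Dice/IoU for classes absent from both
masks are undefined and excluded from means; non-finite training loss
aborts with a diagnostic rather than continuing silently.

## Known limitations

The network runs on CPU in vectorized R; it is intended for method study
and desk-scale experiments, not for training at clinical dataset scale.
Pretrained backbone weights are not loadable (the widths differ from
published checkpoints).  Boundary-distance metrics and layer-thickness
extraction are out of scope.
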