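---
title: "A-DenseUNet: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A-DenseUNet: model, training protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The segmentation problem

Colorectal polyps are the precursor lesion of most colon carcinomas, and
pixel-wise segmentation of polyps in colonoscopy frames is the core
perception task behind computer-aided detection. The input is an RGB frame
$x \in [0,1]^{224 \times 224 \times 3}$; the target is a binary mask $y$
marking polyp pixels. The network produces a probability map through a
sigmoid output,

$$\hat y = \sigma(z) = \frac{1}{1 + e^{-z}},$$

and is trained by default with the pixel-wise binary cross-entropy

$$L = -\sum_{i=1}^{N} \big[ y_i \log \hat y_i + (1 - y_i) \log (1 - \hat y_i) \big],$$

reduced to a mean over pixels and mini-batch in the optimizer (a sum makes
the effective step size depend on image area, which interacts badly with a
fixed learning rate). Soft Dice, soft Jaccard and mean-square losses are
selectable alternatives. Predictions are binarised at 0.5 (boundary
inclusive) and scored with confusion-count metrics:
recall $TP/(TP+FN)$, precision $TP/(TP+FP)$, IoU $TP/(TP+FP+FN)$ and
Dice $2TP/(2TP+FP+FN)$, which satisfy $\mathrm{Dice} = 2\,\mathrm{IoU}/(1+\mathrm{IoU})$
on any single confusion table.

## Architecture

**Dense encoder.** The encoder is a densely connected convolutional network
of depth $s = 5$: a $7\times7$, stride-2 stem with 96 filters, a
$3\times3$ stride-2 max pool, then four dense blocks with layer repeats
$[6, 12, 36, 24]$ at growth rate $k = 48$, separated by transitions
($1\times1$ convolution compressing channels by $\theta = 0.5$, then
$2\times2$ average pooling). Each dense layer sees the concatenation of
everything before it in its block,
$x_t = H_t([x_0, x_1, \dots, x_{t-1}])$, and appends $k$ channels through a
$4k$-wide $1\times1$ bottleneck followed by a $3\times3$ atrous convolution.
For a 224 px input the per-level (side, channels) contract is
$(112, 96), (56, 384), (28, 768), (14, 2112), (7, 2208)$ —
`infer_encoder_shapes()` computes it without building the network, and the
test suite checks the built network realises it exactly.

**Atrous convolution.** Every $3\times3$ convolution is dilated,
$(F *_l k)(p) = \sum_{s + lt = p} F(s)\,k(t)$ with rate $l = 2$ by default,
which widens the receptive field at no parameter cost; a rate-$l$ kernel is
equivalent to a standard kernel inflated with $l-1$ zeros between taps.
`atrous_convolve()` is a direct reference implementation of this sum used by
the verification suite; the network kernels use the same dilation geometry
in compiled code. "Same" zero padding ($l \cdot (k_h - 1)/2$) keeps spatial
sides unchanged so the level contract above holds at any rate.

**Nested decoder with attention.** The decoder is a UNet++-style grid:
level $i \in 1..4$ holds columns $j = 1..5-i$, and node $(i, j)$ fuses the
upsampled output of node $(i+1, j-1)$ with the concatenation of the encoder
output and all earlier decoder nodes at level $i$. Upsampling is a
$2\times2$ stride-2 transposed convolution (exact $\times 2$, no overlap
ambiguity). Before upsampling, the deeper node passes an additive attention
gate — $1\times1$ projections of the gated features and the gating signal
are summed, rectified, projected to one channel and squashed to a
coefficient map in $[0,1]$ that multiplies the features. The gate in the
decoder is self-gating (the deeper node's pre-upsample features serve as
both inputs), which matches the stated placement "before the up-sampling
layer"; the exported `attention_gate()` op is the general two-input form and
resamples a half-resolution gating signal bilinearly. After fusion each node
applies a residual refinement: a $1\times1$ projection shortcut plus a
parallel $3\times3$ atrous convolution → batch norm → ReLU branch.

**Deep supervision head.** Every top-row (level-1) node output is projected
by a $1\times1$ convolution to a common width (32 by default), upsampled
bilinearly to full resolution, averaged elementwise, and passed through a
final $1\times1$ convolution and the sigmoid. The final bias is initialised
at $-2$ so an untrained network predicts a low foreground probability,
matching the class balance of polyp frames.

**Ablation switches.** Three flags remove one architectural addition each
while preserving the output contract: `no_attention` deletes the gates,
`no_dense_links` collapses the grid to a single-column U-Net path, and
`no_dilation` sets every dilation rate to 1 *and* removes the decoder's
dilated-convolution residual branches (leaving the projection shortcut).
The last choice reads the ablation as *block removal*: a pure rate change
would alter no parameters, whereas removing the refinement block is what
"removing the added block" means for a block whose content is the dilated
convolution. Each single-flag ablation therefore has strictly fewer
parameters and an unchanged output shape.

## Why the network core is implemented in this package

No deep-learning runtime is part of this package's dependency set, by
design: the convolution (dilated, strided), transposed convolution, pooling,
bilinear resampling and batch normalisation kernels live in `src/` as
compiled code, and a minimal reverse-mode tape in R differentiates any
composition of them. Every kernel's backward pass is verified against
central finite differences, both op-by-op and end-to-end through the full
network (`test-autograd.R`). This keeps the package self-contained and makes
the numerical behaviour fully auditable.

Batch statistics for normalisation are computed over the spatial positions
of the current image (gradient accumulation proceeds image by image);
running estimates with momentum 0.1 are used at inference, so prediction is
fully deterministic. Batch-norm epsilon is $10^{-5}$; BCE clips
probabilities at $10^{-7}$ before logarithms. Weights are He-initialised
from a generator seeded by `config$seed`, so builds are reproducible.

## Data pipeline and augmentation

Datasets follow the Kvasir-SEG directory convention (`images/`, `masks/`,
matching basenames). Masks are binarised at the 8-bit midpoint (values
> 127 are foreground) — nominally binary masks shipped as compressed images
often carry off-by-a-few artefacts. Ids are split 80/10/10 by a seeded
shuffle, flooring the train and validation sizes and giving the remainder to
test (1000 ids → 800/100/100).

Training-time augmentation resizes with preserved aspect ratio (shorter
side to 224) and takes a random crop, then applies each of the four
techniques independently with probability 0.5: rotation uniform in 0–90°,
horizontal/vertical reflection, elastic deformation on a fixed 10×10
control grid, and random gamma in [0.7, 1.5]. A multiplier of 10 emits the
(deterministically resized) original plus nine variants, so 800 inputs
become exactly 8000 outputs. Geometric transforms hit image and mask
through the identical coordinate field — bilinear sampling with reflect
padding for images, nearest for masks, so masks remain strictly binary.
The per-technique mix, elastic magnitude (6 px standard deviation,
interpolated smoothly between control points) and the gamma interval are
this package's choices where the protocol leaves them open; reflections are
implemented as exact index reversals so a double flip restores the sample
bit-for-bit. Evaluation-time resizing is the deterministic counterpart:
aspect-preserving scale plus centre crop.

## Synthetic phantoms

The phantom generator exists so the whole pipeline is testable without
external data. A sample is a pink-brown mucosa field (smooth low-frequency
noise), one or two raised elliptical polyps with a redder, distinctly
textured, border-smoothed cap, a few saturated specular highlights, and
radial vignetting; the ground-truth mask is the exact union of the
generating ellipse interiors, never re-segmented, so masks are pixel-exact
by construction. Defaults put the foreground fraction roughly between 1%
and 15% of pixels, the range typical of polyp frames. Every sample is a
pure function of `(config, index)`.

What phantoms do *not* emulate: real mucosal vasculature and texture
families, polyp morphology classes (sessile, pedunculated, flat), motion
blur, stool/fluid occlusion, and the label noise of human annotation.
Passing the phantom-based tests therefore demonstrates that the
architecture, gradients, augmentation and bookkeeping are correct — not
that the published real-data scores transfer; those require the external
datasets and GPU-scale training, which are outside this package's scope.

## Training protocol

`train_config()` defaults encode the published recipe: Adam, batch size 10,
up to 100 epochs, learning rate starting at 0.01 and divided by 10 whenever
validation loss fails to improve (min-delta $10^{-4}$) for more than 5
epochs, early stopping on the validation set (15 epochs by default, a
choice the protocol leaves unquantified), best-validation weights retained.
The learning-rate sequence is non-increasing and each drop is exactly the
plateau factor — the test suite asserts both.

`overfit_smoke()` is the package's end-to-end health check: the reduced
architecture (96 px input, $k=8$, blocks $[2,2,2,2]$, narrow stem and
decoder — the full topology at desk scale) memorises 8 phantoms within 300
Adam steps at $10^{-3}$ with mini-batches of 4, stopping once training-set
Dice reaches 0.93. The learning rate differs from the full-scale protocol
because the task differs: memorising 8 images with a 220k-parameter network
is a stability regime where 0.01 overshoots. Problem sizes throughout the
test suite (96 px smoke runs, 32 px gradient checks, 8000-output
augmentation streamed through a sink) were chosen so a single CPU core
completes the whole suite comfortably.

## Known limitations

* The published parameter budget ("11.0 M") is not reproduced and is not a
  target: a $k = 48$, $[6,12,36,24]$ dense encoder alone exceeds it many
  times over, so the full build here is ~62 M parameters. The layer
  arithmetic behind the "DenseNet-164" name is likewise unexplained; the
  printed table of repeats is treated as authoritative.
* The exact wiring of the "horizontal dense connections" is
  under-specified at the published figure's resolution; the nested-grid
  reading implemented here is an interpretation, switchable off via
  `use_dense_decoder_links`.
* Gradient accumulation is per-image (batch statistics over one image's
  pixels), not synchronized batch norm; at batch size 10 this differs
  slightly from framework batch norm.
* CPU-only: no accelerator path. The full 224 px build is practical for
  inference and shape verification; full-scale training at the published
  protocol is a multi-hour GPU task by the original account and is out of
  scope here.
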