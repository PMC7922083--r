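# adenseunet

Pixel-wise polyp segmentation for colonoscopy frames with **A-DenseUNet**:
a densely connected atrous-convolution encoder, a nested multi-depth decoder
with attention-gated connections between depths, and a deep-supervision head
that averages full-resolution outputs from every decoder depth. The package
is aimed at researchers in biomedical image analysis who want a fully
auditable, CPU-only reference implementation of this architecture together
with its training protocol, evaluation metrics, augmentation pipeline and a
synthetic phantom generator that makes the whole pipeline testable without
external data.

## The model in brief

An input frame `x ∈ [0,1]^(224×224×3)` is encoded by a DenseNet-style
backbone (7×7/96 stride-2 stem, 3×3 stride-2 max pool, dense blocks with
repeats [6, 12, 36, 24] at growth rate k = 48, transitions compressing
channels by θ = 0.5), every 3×3 convolution dilated at rate l = 2:

    (F *_l k)(p) = Σ_{s + l·t = p} F(s) k(t)

The decoder is a UNet++-style grid: node (i, j) fuses the attention-gated,
transposed-convolution-upsampled output of node (i+1, j−1) with all
same-level predecessors. Top-row outputs are projected to a common width,
upsampled to full resolution, averaged, and passed through a 1×1 convolution
and sigmoid `σ(z) = 1/(1+e^(−z))`. Training minimises pixel-wise binary
cross-entropy `L = −Σ_i [y_i log ŷ_i + (1−y_i) log(1−ŷ_i)]` (soft Dice,
Jaccard and MSE selectable) with Adam, batch 10, lr 0.01 reduced ×0.1 on a
5-epoch validation plateau, early stopping. Predictions are thresholded at
0.5 and scored by recall, precision, IoU `TP/(TP+FP+FN)` and Dice
`2TP/(2TP+FP+FN)`.

There is no deep-learning runtime dependency: convolutions (dilated,
strided, transposed), pooling, bilinear resampling and batch normalisation
are compiled kernels under `src/`, differentiated by a small reverse-mode
tape and verified against finite differences end to end.

## Worked example

```r
library(adenseunet)

# architecture contract, without building anything
infer_encoder_shapes(model_config())
#>   level spatial_side channels
#> 1     1          112       96
#> 2     2           56      384
#> 3     3           28      768
#> 4     4           14     2112
#> 5     5            7     2208

# desk-scale network on synthetic phantoms
pc      <- phantom_config(side = 96, seed = 0)
samples <- lapply(0:7, function(i) phantom_sample(pc, i))
net     <- a_denseunet(reduced_model_config(seed = 1000))
net
#> A-DenseUNet network
#>   input 96x96x3 -> output 96x96x1 (sigmoid)
#>   depth s = 5, growth rate k = 8, blocks [2, 2, 2, 2]
#>   trainable parameters: 220,023

fit <- fit_adenseunet(net, samples, samples,
                      train_config(batch_size = 4, epochs = 60,
                                   initial_lr = 1e-3, seed = 1))
evaluate_model(fit, samples)
#> segmentation metrics (per-image-mean, n = 8):
#>   Dice 0.9208  IoU 0.8569  Recall 0.8961  Precision 0.9605
```

The Dice/IoU lines say how well the memorised masks are reproduced at the
0.5 threshold, averaged per image; a healthy build overfits 8 phantoms to
Dice ≳ 0.9 within a couple of hundred optimizer steps. `predict(fit, img)`
returns the probability map; `predict(fit, img, type = "mask")` the binary
mask.

A thin command-line wrapper for `synth`, `augment`, `train`, `eval` and
`predict` lives at `inst/cli/adenseunet.R` and works on directories laid out
in the Kvasir-SEG convention (`images/`, `masks/`, matching basenames).

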