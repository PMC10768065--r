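---
title: "Architecture, training objective and evaluation: the methods behind weedseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Architecture, training objective and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedseg)
```

`weedseg` reimplements, from its public description, a lightweight
attention-aided encoder–decoder for three-class (soil/paddy background,
crop, weed) semantic segmentation of field images, together with its
training protocol, metric suite, and a complexity profiler. This vignette
records the model, every place where the design was genuinely open, the
choice made there and why, and what the test suite does and does not
establish.

## The network

The backbone is a symmetric six-stage U-shape with channel plan
{8, 16, 24, 32, 48, 64}. Encoder stage 1 is a Conv2d block (3×3
convolution, batch normalization, GELU) at full resolution. Each stage
*i* ≥ 2 optionally applies the dual attention block, halves the grid with
2×2 max pooling, and extracts features with either a Conv2d block or (in
stages 4–6) the refinement dilated conv block. The decoder mirrors the
ladder with a Conv2d block followed by ×2 bilinear upsampling at each
stage; skip connections are element-wise additions of the (optionally
SCA-gated) encoder outputs. A bare 3×3 convolution maps the final
8-channel map to class logits; softmax is applied only at loss/metric
time.

Three blocks distinguish the architecture:

* **Dual attention (DA).** Branch one projects the input with a 1×1
  convolution + group normalization, multiplies the `N × C` pixel matrix
  by a key memory `M_K` (giving `N × 4C`), applies a softmax **over the
  4C memory slots** so each pixel becomes a convex combination of memory
  rows, reads a value memory `M_V` back to `N × C`, and projects again.
  The memories are shared across all samples — attention about the
  dataset, at cost linear in `N`. Branch two is a channel gate:
  global average pooling, a single 3-tap 1-D convolution slid across
  channels, a sigmoid. Output: `GELU(branch1 + branch2 ⊙ x + x)`.
* **Refinement dilated conv (RDC).** The input is split into four equal
  channel groups; group *k* passes through a depthwise 3×3 convolution
  with dilation rate (1, 2, 5, 8)[*k*] and padding equal to the rate, so
  the spatial size is preserved; the groups are concatenated and fused by
  a pointwise convolution + group normalization + GELU that also sets the
  stage's output channel count.
* **Spatial connectivity attention (SCA).** One 7×7, dilation-3,
  padding-9 convolution (2 input channels, 1 output, scalar bias — 99
  trainable scalars in total) is shared by all six stages. Per stage, the
  channel-wise max and mean maps are concatenated, convolved by the shared
  kernel and squashed to a gate `T ∈ (0,1)`; the stage output is
  `T ⊙ x + x`, so gating can only preserve or amplify, never delete.

Ablation variants (`build_variant()`): `U_VI` (no blocks), `U_VI+RDC`,
`U_VI+DA`, `U_VI+SCA`, `U_VI+RDC+DA`, and the full model
(`U_VI+RDC+DA+SCA`).

## Conventions fixed by complexity accounting

Several micro-decisions are not determined by the block equations alone.
We fixed them jointly so that the exact trainable-parameter counts and
MAC counts of all six variants reproduce the published complexity figures
of the reference design; that accounting turned out to pin the
configuration uniquely:

* **Bias placement.** Encoder Conv2d blocks are bias-free (batch
  normalization's shift absorbs a conv bias, so the parameter is
  redundant); decoder Conv2d blocks and the classifier head carry biases.
  The asymmetry carries no functional weight — it reproduces the
  reference parameter totals (U_VI = 107,187 scalars = 0.1072 M) and is
  harmless because the redundant decoder biases are simply extra shift
  parameters.
* **DA placement.** The dual attention block runs **before** max
  pooling, at the incoming stage's full resolution. The alternative
  (pool first, attend at the reduced grid) costs 4× less but is
  incompatible with the reference MAC counts, which match the pre-pool
  placement exactly.
* **DA internals.** Both 1×1 projections are bias-free and their group
  normalizations carry no affine parameters; the value-memory read adds a
  learnable length-`C` bias (`Y = A M_V + b_V`); the channel 1-D
  convolution is bias-free (the convention of efficient channel
  attention). Per block: `10C² + C + 3` scalars.
* **RDC internals.** The four branch convolutions are depthwise (one
  3×3 kernel per channel) with per-channel biases; the pointwise fusion
  is bias-free with an affine-free group normalization. Per block:
  `10·C_in + C_in·C_out` scalars. The channel-raising role of the
  replaced Conv2d block moves into the fusion, so the divisibility-by-4
  constraint applies to the input channels. RDC replaces the Conv2d
  block in encoder stages 4–6.
* **Decoder order.** Each decoder stage convolves at the coarse
  resolution and then upsamples (4× cheaper than the reverse, and the
  configuration the reference MAC counts imply).
* **Normalization.** Conv2d blocks use batch normalization with affine
  parameters (eps 1e-5, momentum 0.1, running statistics for inference);
  DA and RDC use 4-group group normalization without affine parameters
  (eps 1e-5), which is batch-size independent.

One discrepancy in the reference complexity table is irreconcilable: for
the RDC-bearing variants the published MAC reduction (−15.6 M at 256²)
exceeds the largest reduction any architecture consistent with the
published *parameter* reduction can produce in stages 4–6 (−12.5 M), and
moving RDC into stage 3 to recover the MACs breaks the parameter count.
`weedseg` reports its own self-consistent counts for those variants
(`U_VI+RDC` 0.1112 G, full model 0.2446 G, which still rounds to the
headline 0.24 G); the baseline and the DA/SCA variants match the
published figures at four decimals.

## The FLOP convention

`count_flops()` is analytic and uses the convention of the common PyTorch
profilers (1 FLOP = 1 MAC):

| operation | cost |
| --- | --- |
| convolution | `out_elems · k² · C_in / groups` (+1/elem if biased) |
| matrix product `N×a · a×b` | `N·a·b` (bias free) |
| batch normalization | 2 per element |
| global average pooling | 1 per input element |
| group norm (affine-free), activations, softmax, pooling, interpolation, elementwise products | 0 |

Counts are per image (batch 1) at a stated input size, 256×256 by
default; input sides must be divisible by 32 (five 2×2 poolings).

## Losses

The training objective is `0.8 · Dice + 0.2 · CE` on softmaxed logits.
The published definition sums over all `B·H·W` pixels without stating a
class treatment or reduction, so:

* **Dice** is computed per class over all pixels of the batch against the
  one-hot target, then averaged over the three classes. A `smooth = 1e-6`
  is added to each denominator so a class absent from both prediction and
  target contributes zero loss instead of 0/0.
* **Cross-entropy** is the mean over pixels of the negative log predicted
  probability of the true class, clamped at 1e-12.

Both reductions are means, so the 0.8/0.2 mixing weights keep the same
relative scale at any batch or image size. The compound loss is exactly
the stated affine combination for any weights (a tested identity), is
zero only for a perfect one-hot prediction, and its analytic gradient
matches central differences to 1e-5 on random logits in [−10, 10].

## Metrics

Evaluation aggregates per-class one-vs-rest confusion counts (TP, FP, FN,
TN) over the *whole* image set first and computes metrics from the
aggregate — the convention under which per-class counts add up to a single
dataset-wide pixel total. Conventions not determined by the formulas:

* zero denominators: a class absent from truth *and* prediction scores 1
  on every metric (nothing was missed); any other zero denominator scores
  0;
* masks are scored at their native resolution — predictions produced at
  the network input size are upsampled to the mask size with
  nearest-neighbour sampling first;
* `IOU = F1/(2 − F1)` holds exactly on raw counts and is asserted to
  1e-9 over randomized confusion tables. (Applying it to an F1 value
  already rounded to four decimals can move the fourth decimal of the
  IOU by one unit — an input-rounding artifact, not a property of the
  identity.)

## Training protocol

AdamW with decoupled weight decay (betas 0.9/0.999, eps 1e-8 — optimizer
defaults, since none are published), lr 0.001, weight decay 0.01, batch
size 6, 150 epochs. The cosine schedule is evaluated per epoch with the
epoch count as its period, decaying from lr to 0; per-step annealing is
the noted alternative. Checkpoints are written every 5 epochs and at the
end; when a validation set is supplied, the best-validation-MIOU
checkpoint is kept as well (model selection is not published; keeping
both last and best is the safe default). Validation history records both
pixel accuracy and MIOU since "accuracy" alone is ambiguous. Runs are
fully reproducible on one device for a fixed seed; checkpoints restore
forward passes bit-identically.

## Synthetic scenes: what they emulate, and what a green test means

The generator (`scene_spec()`, `generate_synthetic_scene()`) emulates the
*structure* of robot- and UAV-acquired field datasets: a textured brown
soil (or green-blue paddy) background, a few large rosette-shaped crop
plants, and many small, thin, scattered weed blades, with optional
weed-on-crop overlap and optional paddy "reflections" that stay labelled
as background. Defaults at 256²: 3 crops of radius 24–40 px, 12 weeds of
radius 4–9 px, 10% overlap probability, additive noise sd 0.04 — chosen
once as plausible magnitudes for a sugar-beet-field view and not tuned
afterwards; the learning-capability test uses the same world scaled to
64² (2 crops at radius 8–12, 6 weeds at radius 2–4). Weed blades are
rendered in a lighter, yellower green than the crop rosettes, a mild
spectral cue consistent with different species.

Deliberately absent: occlusion by soil clutter, illumination variation,
motion blur, species diversity, label noise, and the scale of real
datasets. A green test therefore establishes that the architecture,
gradients, training loop and metrics are *correct and able to learn* —
the overfitting test reaches MIOU > 0.9 on its own training scenes within
500 steps — not that the network attains any particular accuracy on real
field data, which requires the real datasets and GPU-scale training.

## Numerical choices

* GELU is exact (`x·Φ(x)`), not the tanh approximation; its derivative
  reuses the forward pass's Φ.
* Softmaxes subtract the row maximum before exponentiation.
* Argmax over class logits breaks ties toward the lower class index;
  channel-max pooling in SCA breaks ties toward the lower channel (both
  deterministic).
* Memory units initialize from N(0, 1/C); convolutions and biases use
  the fan-based uniform default `U(±1/√fan_in)`; norm affines start at
  identity.
* Max pooling requires even spatial sides; the network requires sides
  divisible by 32 and says so in its error message.
* All-zero inputs are safe everywhere: group norm maps zeros to zeros
  (variance 0 is regularized by eps), and GELU(0) = 0.

## Known limitations

* CPU-only and R-speed: a full-scale 150-epoch training on a real
  dataset is out of reach; the package targets desk-scale verification,
  methodological reuse, and small fine-tuning experiments.
* RGB only — multispectral bands are not modelled.
* The published complexity table's RDC rows cannot be reproduced
  exactly (see above); all other printed figures are matched at four
  decimals.
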