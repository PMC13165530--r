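---
title: "Dual-gated fusion and boundary refinement for polyp segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-gated fusion and boundary refinement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Colorectal polyps are segmented from endoscopy frames under two coupled
difficulties. First, a *semantic gap*: deep encoder features localize the
lesion but are spatially coarse, while shallow features carry boundary
detail but also mucosal texture, vessels and specular noise, so naive
cross-level fusion misplaces the lesion. Second, *boundary ambiguity*:
flat or camouflaged polyps have weak intensity contrast against the
surrounding mucosa, so even a well-localized prediction has blurred
contours. `dsfbr` implements an **align-then-refine** architecture that
addresses the two in order: cross-level features are gated and aligned
before any high-frequency edge information is injected.

## The model

An encoder produces stage maps at strides 4/8/16/32. A 1×1
convolution–batchnorm–ReLU (CBR) block per stage reduces every map to a
common width `C` (default 32), giving the pyramid `f1..f4`. Convolutions
that are followed by batch normalization carry no bias; the normalization
shift subsumes it.

**Dual-Gated Semantic Fusion (DSF).** Each decoder step fuses a high-level
map with the next lower-level map:

* `Fin = upsample(CBR1(f_hi)) + CBR1(f_lo)` — bilinear upsampling
  (align-corners off) everywhere;
* a channel gate `Mc = sigmoid(Conv1D(GAP(Fin)))` — an efficient-channel-
  attention gate: global average pooling to a length-`C` descriptor and a
  1-D convolution across channels with **no dimensionality reduction**.
  The kernel size follows the adaptive rule (nearest odd integer to
  `log2(C)/2 + 1/2`), which gives `k = 3` at `C = 32`; the 1-D convolution
  uses replicate padding (the rule's padding is unstated in the
  literature; with `k = 3` the end effect is negligible) and no bias;
* a spatial gate `Ms = sigmoid(Conv7x7([avgpool_c; maxpool_c](Fin)))` with
  zero padding 3 and a bias (no normalization follows it);
* the output `x = CBR3x3(Fin + Fin ⊙ Mc ⊙ Ms)` — a residual path
  guarantees that for nonnegative `Fin` the pre-smoothing tensor lies
  between `Fin` and `2·Fin` elementwise, so gating can only re-weight, not
  erase.

The cascade is top-down: `x4 = DSF(f4, f3)` at stride 16,
`x3 = DSF(x4, f2)` at stride 8, `x2 = DSF(x3, f1)` at stride 4. The
pairing is the natural reading of the architecture diagram; the
alternatives (e.g. fusing `f4` with `f2`) would skip a stage and break the
stride-halving contract.

**High-frequency Boundary Refinement (HBR).** A coarse head (two 3×3 CBRs
and a 1×1 convolution) on `x2` produces a coarse probability map. Fixed,
non-trainable 3×3 Sobel kernels applied to that map give an edge magnitude
`sqrt(gx² + gy² + δ)` (δ = 1e-12 keeps the root differentiable at zero; an
`|gx|+|gy|` combination is available by configuration), and a sigmoid
yields the edge mask `Medge`. Because the magnitude is nonnegative,
`Medge` lives in [0.5, 1) and equals 0.5 exactly on flat regions — this
floor is a property of the stated construction, not a bug; the Dice-based
edge supervision rewards relative contrast, so the floor is benign. A
"centered" variant (`sigmoid(magnitude − τ)`) is exposed behind a
configuration flag and off by default. The Sobel convolutions use
replicate padding so image borders do not fire as spurious edges.

Shallow features are injected under the mask's guidance:
`f_edge_scaled = α · (CBR3x3(f1) ⊙ Medge)` with a single learnable scalar
`α` initialized at 1 (the edge branch is active from the start and free to
shrink), and `prediction = Conv1x1(CBR3x3(CBR3x3(x2) + f_edge_scaled))`.
`Medge` itself is the supervised edge prediction; there is no separate
edge head.

**Deep supervision.** Auxiliary 1×1-conv heads on `x4` and `x3`, the
coarse map, and the final prediction are all supervised at full input
resolution (logits bilinearly upsampled; the supervision resolution is a
design choice — supervising at native stride resolutions is the main
alternative and would change only constant factors in the loss).
The stored coarse probability is exactly the sigmoid of the upsampled
coarse logits, so losses can be computed from logits in the numerically
stable form without any drift from the reported probability.

## Losses

The structure loss on every semantic head is `wBCE + wIoU` with **unit
weights** (no balancing coefficient). The pixel weighting is
`ω = 1 + 5·|meanpool31(G) − G|`: pixels whose label disagrees with their
31×31 neighbourhood mean — boundary and isolated pixels — are
up-weighted. The mean pooling normalizes by the true window overlap at
borders, so a constant mask gives `ω ≡ 1` exactly and weighted BCE reduces
to plain BCE there. The weighted soft IoU uses the same `ω` on
intersection and union with a small `1e-6` smoothing; an exact soft-IoU
semantics was preferred over the `+1` smoothing used in some reference
code bases because it preserves the textbook half-overlap arithmetic
(loss = 1 − 2/6 for |P|=|G|=4 with overlap 2) while the degenerate
empty/empty case still returns 0.

The edge branch uses a Dice loss with smoothing `ε = 1e-5`:
`1 − (2ΣE·Gedge + ε)/(ΣE + ΣGedge + ε)`. The edge ground truth is the 3×3
morphological gradient of the mask (dilation minus erosion, replicate
padding), a 1–2 px contour band; the band width is configurable in
principle but the default is not dilated further — the Sobel response of a
step is 2 px wide, which the 1–2 px band already matches.

The total loss is the plain sum of the structure losses of every head the
variant produces plus the edge Dice term. Variants without a head omit
that term (the ablation baseline is supervised only through its single
prediction head).

## Backbones

Two encoders are registered. `pvtv2-b2` is the Pyramid Vision Transformer
v2 at b2 capacity — embed dims 64/128/320/512, depths 3/4/6/3, heads
1/2/5/8, MLP ratios 8/8/4/4, spatial-reduction ratios 8/4/2/1, qkv bias —
which this package builds with faithful parameter shapes (24.85 M
parameters, the standard backbone-only figure) and a full inference
forward pass. Backpropagation through the transformer is not implemented:
training with this backbone updates the decoder only, a frozen-backbone
regime. `tiny-cnn` is a four-stage CNN (widths 16/24/32/48; a stride-4
stem followed by three stride-2 stages, each with a refining 3×3 CBR) that
is fully differentiable end to end and exists so the complete graph —
fusion gates, Sobel refinement, deep supervision — trains on one CPU in
minutes. All layers and gradients are implemented on plain R arrays with
BLAS matrix products; gradient correctness is pinned by finite-difference
tests through the entire graph.

With the PVTv2-b2 backbone and the C = 32 decoder the full model counts
24.96 M trainable parameters (backbone 24.85 M + decoder 0.11 M; the fixed
Sobel kernels are buffers, not parameters). Larger decoder widths raise
the decoder share roughly quadratically in C (0.39 M at C = 64); C = 32
keeps the backbone dominant, which is the design intent of an efficiency-
oriented architecture.

## Synthetic phantoms

The generator emulates the specific failure modes of endoscopy, not its
photometry: a smooth low-frequency "mucosa" field (four random low-order
harmonics over a pinkish base) with a radial vignette; one star-convex
lesion whose boundary radius is perturbed by Fourier modes 2–8 with total
relative amplitude ≤ 0.2 (so the lesion area stays within provable bounds
of the nominal disc); an intensity shift δ between lesion and mucosa,
blended over a boundary of softness `b` (a Gaussian blur of the blend
weight); small saturated ellipses as specular highlights; Gaussian texture
noise. The binary mask is the pre-blur lesion support and the edge map its
morphological gradient, so mask/edge consistency is exact by construction.

Three presets name the lesion phenotypes: `easy` (δ = 0.4, hard boundary),
`camouflage` (δ = 0.05, boundary softness 3 — the flat/camouflaged
phenotype that motivates the gating), and `small` (radius 5–10% of the
side). Phantoms are deterministic given seed and parameters.

What the phantoms do **not** contain: real mucosal texture statistics,
specular geometry tied to illumination, motion blur, instrument shadows,
or multi-lesion clutter (a multi-lesion flag exists but is off by
default). Passing the desk-scale tests therefore demonstrates that the
architecture, losses, metrics and training loop are implemented correctly
and that the components interact as claimed (gating helps most when
contrast is low); it does not certify benchmark performance on clinical
data, which requires the public datasets and GPU-scale training that are
out of scope here.

## Training protocol

AdamW (weight decay 1e-5), initial learning rate 1e-4 at full scale,
cosine annealing to zero after a 5-epoch linear warmup
(`lr(t) = lr0·t/5` for `t ≤ 5`, then `lr0·(1 + cos(π(t−5)/(T−5)))/2`),
batch 16 at 352×352, 150 epochs, early stopping after 30 stagnant
validations of mDice, every stage seeded. Augmentation applies one
geometric draw to image and mask alike: horizontal/vertical flips (p = 0.5
each), right-angle rotation composed with scale jitter from
{0.75, 1, 1.25} with resize-back ("multi-scale rotation" is ambiguous in
the protocol's usual wording; the right-angle-plus-jitter reading is the
convention of the model family this protocol follows), and cutout of one
rectangle of at most 25% area (p = 0.3, image only — masking the label
would corrupt supervision). Masks are resampled nearest-neighbour and stay
binary. Images are standardized channel-wise with the fixed natural-image
statistics (0.485/0.456/0.406, 0.229/0.224/0.225). When no validation
directory is given, a seeded 10% holdout is carved from the training
split.

### Desk-scale defaults

CPU-scale runs — the package's test suite and acceptance script — use the
same engine at reduced sizes, chosen once as what one CPU core handles in
minutes: 96×96 inputs, batch 8, 10 epochs, lr 1e-3 (the shorter schedule
needs the larger step), 120 easy-preset training phantoms and 40 held-out;
for the six-variant ablation, 64×64 camouflage phantoms (64 train /
24 validation), 8 epochs, 2 seeds. The `tiny-cnn` backbone is used for all
training tests. Thresholds are not adjusted for scale: the easy-preset run
must reach held-out mDice ≥ 0.85, and the ablation must reproduce the
component ordering (baseline ≤ +HBR ≤ full, baseline ≤ +DSF ≤ full,
gate-ablated variants ≤ full) with a soft margin of 0.03 mDice for seed
noise, with the full-vs-baseline gap required outright.

## Metrics

Per-image Dice and IoU are computed on the prediction thresholded at 0.5
(the threshold is a convention; the continuous map is kept for the
structure measures) and averaged arithmetically over images. The
`Dice = 2·IoU/(1 + IoU)` identity is asserted exactly on binary pairs. If
a ground truth is empty, the score is 1 when the prediction is empty too
and 0 otherwise — needed for synthetic edge cases; benchmark ground truths
are never empty.

The structure-quality measures follow their original definitions:
weighted F-measure (β² = 1) with the dependency weighting built from an
exact Euclidean distance transform (two-pass parabola algorithm with
nearest-site indices) and a 7×7 σ = 5 Gaussian; S-measure with balance
α = 0.5 (object term plus 4-quadrant region SSIM at the mask centroid);
E-measure computed on the continuous map and averaged (the mean variant;
whether a benchmark reports mean or max E-measure varies, and the choice
is flagged in the report header). Each measure is clamped to [0, 1]; the
E-measure's original divisor `H·W − 1` makes perfect agreement score
marginally above 1 before clamping, so clamping makes the perfect case
exactly 1.

## Numerical choices and degenerate inputs

* Bilinear resizing is separable with align-corners off; its adjoint is
  used as the gradient, so upsample/downsample pairs are exactly
  transposed.
* Batch normalization uses biased batch variance in the training pass and
  keeps unbiased running statistics for inference.
* The channel-max pooling in the spatial gate routes its gradient to the
  argmax entry only; ties resolve to the lowest channel index.
* Empty masks: the edge target of an empty (or full-frame) mask is empty;
  the Dice loss's ε guard returns 0 for the empty/empty case; loss
  gradients stay finite at both degenerate masks (asserted by test).
* Checkpoints store the config, every tensor (including the fixed Sobel
  buffers) and batch-norm running statistics; a reload reproduces
  evaluation bit-for-bit.

## Known limitations

* Training through the PVTv2-b2 backbone is not implemented (decoder-only
  updates); end-to-end fine-tuning requires a framework with transformer
  backprop.
* Pure-R training is CPU-bound at roughly 1–2 s per 96×96 batch of 8;
  the engine is meant for desk-scale verification and method study, not
  benchmark training.
* The phantom generator is a study instrument, not an endoscopy simulator;
  conclusions about clinical data require the real benchmarks.
* The E-measure choice (mean, continuous map) and the 0.5 binarization
  threshold are conventions; numbers are comparable across runs of this
  package but not necessarily digit-identical to other toolkits'
  evaluation scripts.
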