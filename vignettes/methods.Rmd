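---
title: "Methods: a 2D structured state-space segmentation network for tongue images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a 2D structured state-space segmentation network for tongue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Problem

Tongue segmentation is the first computational step of automated TCM
tongue diagnosis: extract the tongue region from a phone photograph so
that downstream shape/coating/color analysis sees only tongue pixels.
Phone photos are uncontrolled — arbitrary lighting and angle, partial
tongue exposure, twisted poses — and the hard pixels are exactly where
lips, skin and tongue meet at nearly the same hue. `tongueseg` implements
an encoder–decoder network for this two-class problem together with its
losses, metrics, and a synthetic-data harness, entirely in R with compiled
kernels, so that the whole loop is testable on one CPU.

## The state-space core

A linear time-invariant system `x' = Ax + Bu, y = Cx + Du` compresses the
input history into an N-dimensional state. We initialize `A` with the
HiPPO (Legendre) construction: entry magnitudes `sqrt((2n+1)(2k+1))` below
the diagonal, `n+1` on it, zero above, and `B[n] = sqrt(2n+1)`.

Two printed-form ambiguities had to be resolved, and both resolutions
follow the S4 literature this construction comes from:

* **Sign.** The construction as usually printed has a positive spectrum,
  i.e. an unstable continuous system. We store `A` negated; all entry
  checks in the tests use magnitudes, so they hold under either
  convention.
* **Input gain of the discretization.** We use the bilinear (Tustin)
  transform `Ā = (I − Δ/2 A)⁻¹(I + Δ/2 A)` with `B̄ = (I − Δ/2 A)⁻¹ Δ B`.
  The `Δ` factor on `B̄` matters: without it the Δ→0 limit does not
  degenerate to "identity dynamics, vanishing input gain", and a
  learnable step size could not trade off kernel length against gain.
  The discretization method is an enum with a single `"bilinear"` member,
  so a zero-order-hold variant can be added without an API change.

The kernel `K̄ = (C̄B̄, C̄ĀB̄, …)` is materialized by iterated state
propagation (never explicit matrix powers), and causal convolution is
evaluated by zero-padded FFT; the stepwise recurrence acts as the
independent oracle for that path throughout the tests. A
diagonal-plus-low-rank path (`A = V⁻¹ΛV − PQᵀ`, rank 1 for HiPPO, Cauchy
dot products through a Woodbury resolvent, inverse FFT at the roots of
unity, with a dense fallback at `z = −1`) is implemented and validated
against the naive path; the naive path is the default because desk-scale
kernel lengths make it both affordable and unambiguous.

## Two-dimensional extension

The 2D kernel is the contraction-weighted sum of outer products of two
independent axis kernels, `K̄(d₁,d₂) = Σₙ C̄ₙ K̄ₓₙ(d₁) K̄ᵧₙ(d₂)`, one SSM
pair per feature channel (depthwise). Decisions made where the design was
open:

* **Causality.** The kernel is anchored at the origin and applied as the
  direct product of two causal 1D convolutions (zero-pad, FFT, crop the
  top-left window). A bidirectional variant (sum of forward and flipped
  kernels per axis, centered application) is a constructor flag, default
  off.
* **Channel mixing.** The depthwise S4 layer replaces a 1×1 convolution,
  which mixed channels; a pointwise convolution after the S4 layer
  restores that capacity. The ablation switch `use_s4 = FALSE` restores
  the original single 1×1 convolution.
* **Resolution flexibility.** Kernels are regenerated from the continuous
  parameters at the incoming extent on every forward pass — the same
  layer runs on 16×16 and 32×32 maps with no weight surgery. A property
  test documents (not proves) the consistency of kernels materialized at
  H and 2H: bilinear taps sit at half-sample phases, so the fine kernel is
  compared pairwise-summed against the coarse one.

## Encoder

Four stages at strides 4/8/16/32 with channels 32/64/160/256, block
depths 3/3/5/2 and feed-forward expansion ratios 8/8/4/4. The attention
block is: pre-norm → 5×5 depthwise convolution → three parallel strip
convolution branches (1×k then k×1, k = 7/11/21) summed with identity →
the S4-2D mixing slot → multiplicative gating of the normalized input →
residual with drop-path (rate 0.01). The strip kernel sizes, stem (two
stride-2 3×3 convolutions) and stride-2 downsamplers are the established
convolutional-attention defaults; they live in `encoder_config()` so that
deviations are configuration, not code. Normalization is batch norm with
epsilon 1e-5 and momentum 0.1. No pretraining anywhere.

## Decoder

The published source of this design gives the decoder's topology only at
block-diagram level; the reading implemented here is: three transpose-conv
up-blocks fuse stages 4→3→2→1 (concatenate skip, two 3×3 convolutions,
projected residual), then a full-resolution path — stride 4 is still two
octaves above the pixel grid — of two further 2× transpose convolutions
with a shallow skip computed from the input image itself, then a 1×1
two-class head. Decoder widths mirror encoder widths on the way up
(configurable). Transpose convolution (kernel 2, stride 2) is the default
upsampler. The original Hamburger-style decoder of the backbone exists
only as a guarded configuration stub (`decoder_kind = "ham"`), since the
shipped configuration is the UNETR-style decoder.

## Losses and metrics

Cross-entropy over the two classes is the shipped loss (`alpha = 1`). The
boundary loss is the mean over pixels of `φ_G · s_θ`, where `φ_G` is the
signed Euclidean distance to the ground-truth boundary (boundary pixels =
foreground pixels with a background 4-neighbor; `φ = 0` there, negative
inside, positive outside, computed exactly by brute force over boundary
pixels — masks are desk-scale). The mean, not the sum, keeps the loss
scale resolution-independent. `combined_loss(…, alpha)` interpolates
linearly; `alpha` is constant by default (no schedule is prescribed for
the mix, and the shipped model does not use the boundary term).

Dice, mIoU and pixel accuracy are computed from integer confusion counts.
Empty-region convention: a ratio with zero denominator is 1 when the
class is absent from both masks and 0 when absent from exactly one; this
keeps the metrics defined on degenerate synthetic fixtures. Test-set
aggregation is **micro** (counts accumulated globally) by default with
macro (per-image mean) behind a flag; the choice is not documented in the
source setting, so the default is declared, not inferred.

## Synthetic data

The generator renders superellipse-based tongue blobs with the edge
modifiers that make real tongue photos hard: sinusoidal radial scalloping
(tooth-marked), an inward tip notch, area-preserving shear/rotation
(twisted), whitish central coating, dark pigment spots, lip-colored bands
hugging the upper boundary, face-tone background with clutter blobs,
brightness/temperature jitter and pixel noise. Semi-axes are normalized
analytically (superellipse area formula × the modifier's mean-square
radius) so the rendered mask area tracks the requested `scale_fraction`
within a few percent.

Two deliberate realism choices:

* **Lip color.** Lips are rendered similar in hue to the tongue but
  darker and more saturated (a 60/40 mix with a dark lip tone). An early
  version used the *identical* color with no luminance edge, which makes
  the boundary information-theoretically unrecoverable — no annotator
  could draw it either — and is harder than the condition the generator
  is meant to emulate.
* **No augmentation.** The training protocol emulated here uses none; the
  generator's own diversity substitutes. `ts_train()` accepts an
  `augment` hook, default off.

What a green test establishes: that the implementation optimizes,
generalizes across the generator's variation axes, and respects its shape
and metric contracts. It does **not** establish clinical performance —
nothing synthetic reproduces real skin/tongue statistics, specular
highlights, teeth, or annotation noise, and the quantitative accuracy
reported for the private clinical dataset is out of scope by design.

## Numerical and training choices

* FFT convolutions pad to the next power of two ≥ H + H_k − 1 (no
  wraparound aliasing; cheap transform lengths).
* S4 parameters per channel: contraction weights `~ N(0, 1/N²)` and log
  step sizes log-uniform on [0.001, 0.1] (the standard S4-family range);
  HiPPO `A`, `B` are fixed buffers.
* Step-size gradients are propagated analytically through the bilinear
  transform (the state recurrence carries `∂s/∂Δ` alongside `s`).
* AdamW: lr 1e-4, betas (0.9, 0.999), batch 16 (the published settings);
  decoupled weight decay 0.01 applied only to ≥2-D tensors — biases, norm
  affines and S4 step sizes are exempt. Constant learning rate; epoch
  count (default 100) and training resolution (default 256, any multiple
  of 32) are this package's own defaults, declared because the source
  setting does not report them.
* The 8:2 split uses round-half-up (416 → 333/83); the alternative
  332/84 rounding is equally consistent with "8:2", so the convention is
  documented rather than inferred.
* Inference reflect-pads any image to stride-32 divisibility and crops
  the logits back; training requires stride-32 inputs directly.
* Batch-norm eval statistics come from standard running averages, so
  early-epoch eval metrics slightly lag train-mode behavior.

## Known limitations

* CPU only, desk scale; no mixed precision, no distributed training.
* Zero-order-hold discretization and the Hamburger decoder are config
  stubs, not implementations.
* The O(L+N) complexity advantage of the Cauchy path is not benchmarked
  (explicitly out of scope); at desk-scale lengths the naive path is
  faster in practice.
* Binary (tongue vs background) only; no tongue-substructure classes.
* The synthetic world is a caricature tuned to failure modes, not a
  simulator; conclusions about clinical accuracy require real data.
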