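---
title: "Multi-channel landmark conditioning for fundus image synthesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-channel landmark conditioning for fundus image synthesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the conditioning
scheme and adversarial models it implements, the assumptions behind the
phantom simulator, the numerical conventions that had to be pinned down,
and the design decisions that were genuinely open.

## The conditioning scheme

The package synthesizes color fundus photographs from binary landmark
masks. Three landmarks are used: the vessel tree, the optic disc, and the
optic cup. The central modeling choice is how these masks enter the
generator:

* **MCML (multi-channel, multi-landmark)** — the three masks occupy three
  separate channels of one conditioning image, in the fixed order (vessel,
  disc, cup). Stacking is lossless: a pixel belonging to both a vessel and
  the disc is marked in both channels, and `mcml_channels()` inverts
  `compose_mcml()` exactly. The channel order itself is arbitrary; any
  fixed order carries the same information, so the package pins one and
  the tests pin it too.
* **One-channel fusion** — disc painted at intensity 128, vessel at 255 on
  top. A vessel pixel inside the disc is then indistinguishable from one
  outside it. This information loss is the point: the baseline exists to
  show what fusing landmarks costs.
* **Vessel-only** — the historical baseline: the vessel mask alone.

Masks enter the networks as −1/+1 values and 8-bit images as
linearly rescaled [−1, 1] values; the generator ends in `tanh`, so its
output lives on the same scale and `denormalize_image()` maps back to
quantized 8-bit RGB. This symmetric scale is the standard convention for
image-translation generators and keeps the zero point mid-gray.

## Generators, discriminator, objectives

Four generator families are provided, all fully convolutional and
shape-preserving:

* **U-net** — stride-2 convolutional encoder/decoder with skip
  connections between matching resolution levels. The depth rule is
  `log2(size) − 1` levels (5 levels at 64 px, 8 at 256 px), which leaves a
  2×2 bottleneck; feature widths double per level and are capped at eight
  times the base width. Decoding uses nearest-neighbour upsampling
  followed by a 3×3 convolution rather than transposed convolution, which
  avoids checkerboard artifacts and needs only one convolution primitive.
* **ResNet-6 / ResNet-9** — a 7×7 stem, two stride-2 downsamplings, then
  6 or 9 residual blocks at the bottleneck resolution, and a mirrored
  decoder.
* **ResU-net** — the U-net with `n_res_blocks` residual blocks (1–3)
  *inserted* at each resolution level: after each down-convolution and
  after each non-outermost up-convolution. Each residual block is the
  identity-shortcut unit `x_{l+1} = x_l + F(x_l)`, with `F` two rounds of
  3×3 convolution, batch normalization and ReLU. Insertion (rather than
  replacing the per-level convolutions) makes the one-block ResU-net
  strictly larger than the plain U-net at equal width, so the residual
  capacity is an addition, not a reshuffling; with all residual weights
  zero each block is exactly the identity, which the tests assert.

The discriminator is a patch classifier: stride-2
convolution/normalization/leaky-ReLU layers (widths doubling from a base,
four layers at 256 px, fewer at small sizes) ending in a 1-channel
convolution and a sigmoid. It consumes the channel-concatenation of the
conditioning input and a candidate image and emits a spatial map of
real/fake probabilities; at all-zero parameters that map is exactly 0.5
everywhere.

Objectives use natural logarithms throughout (losses in nats). The
discriminator minimizes binary cross-entropy against labels real = 1,
fake = 0; at uninformative output 0.5 its loss is exactly `2 ln 2`. The
paired generator objective is the adversarial term plus `λ · L1` with
λ = 0.5 by default. Two adversarial variants are exposed: the literal
minimized term `mean log(1 − D)` — kept because it is the exact formula
the closed-form tests check — and the non-saturating `−mean log D`, the
training default, because the literal form has vanishing gradients
whenever the discriminator wins early. Unpaired training uses two
generator/discriminator pairs with the two-directional cycle-consistency
L1; its weight defaults to 10, the convention of the cycle-consistent
translation literature, since no value is forced by the paired setting
(the paired λ = 0.5 is kept separate and is not reused). An optional
MSE-only warm-up phase for the generator (`mse_warmup_iters`, default 0)
is provided; a least-squares adversarial reading of "initialize G with
MSE" would also be defensible, but warm-up is the interpretation that
leaves the adversarial objective untouched, so it is the one implemented.

## The network engine

No deep-learning framework is part of this package's dependency set; the
package carries its own small engine: im2col/col2im convolution
(forward, input-gradient and weight-gradient) in C++ via RcppArmadillo,
nearest-neighbour upsampling with its exact adjoint, leaky/plain ReLU,
tanh, clamped sigmoid, batch normalization, and Adam. Three conventions
matter:

* **Normalization** uses within-sample spatial statistics (instance-style)
  during training — exact for the batch-size-1 recipe used everywhere —
  while running means/variances accumulate for inference, so synthesis is
  deterministic and repeated calls are bit-identical.
* **Gradient checking**: every layer's backward pass was verified against
  central finite differences during development, and the test suite
  asserts that one backward pass delivers a finite, non-null gradient to
  every trainable parameter of every architecture.
* **Cache discipline**: each layer keeps a LIFO stack of forward caches,
  so one set of weights can be run forward several times before the
  matching backwards — cycle-consistent training traverses each generator
  twice per update, and the last-in-first-out order makes those two
  traversals compose correctly.

Weights initialize from a zero-mean Gaussian with standard deviation 0.02
(the convention of the conditional-GAN lineage), biases and normalization
offsets at zero, normalization gains at one; all draws come from the
config seed. The sigmoid clamps its output to [10⁻⁶, 1 − 10⁻⁶] so the
log-losses stay finite; the clamp is orders of magnitude below every
tested tolerance.

## Training recipe

Adam with learning rate 2·10⁻⁴, β₁ = 0.5, β₂ = 0.999; batch size 1; no
dropout; constant learning rate; 200 epochs by default. Per batch the
discriminator is updated first, then the generator — the order is a
convention fixed for reproducibility. Unpaired training iterates
`max(|A|, |B|)` times per epoch, wrapping the smaller domain, with both
domains permuted independently under the seed. No augmentation is applied
by default: the phantom generator can produce arbitrarily many distinct
samples, so resize-crop jitter would only blur the controlled-experiment
semantics of the fixtures.

## The phantom simulator

The phantom provides paired data with exact ground truth so the whole
pipeline is testable without clinical datasets. It emulates, in layered
painting order: a dark background outside a circular fundus field; a
reddish-orange base field with a radial vignette (illumination falloff);
a brightened disc; a further-brightened cup; dark-red vessel strokes on
top (vessels remain visible crossing the disc, as in real photographs);
additive Gaussian pixel noise, clipped and quantized to 8 bits. Flat
per-region colors make the intensity ordering *cup > disc rim > fundus
field* exact at zero noise, so tests can assert it without tolerance.

The vessel tree grows by recursive binary branching: root trunks run from
the disc center to points on the disc boundary (sharing the center keeps
the whole tree one connected component), then branch outward with
per-level angle jitter and multiplicative stroke-width decay, clipped to
the fundus circle. Root count, recursion depth, root width, jitter and
decay are all parameters; the defaults (3 roots, depth 6, width ≈
size/85 px, 12° jitter, decay 0.8) were chosen once to give a visually
plausible tree occupying a few percent of the field at 256 px, and are
not tuned thereafter. Disc and cup are concentric filled ellipses
(circles by default); the cup radius is `round(cdr × disc_radius)`, so
the equivalent-radius ratio `sqrt(cup area / disc area)` recovers the
requested CDR to within rasterization error — under 5 % relative for
disc radii of 20 px and up, which the tests check.

`generate_dataset()` derives one sub-seed per sample from the dataset
seed (a small hash, kept below 2³¹), so generation is order-independent
and bit-reproducible. The `shared_vessel` flag grows a single vessel tree
from the *base* disc geometry and reuses it while per-sample disc/cup
geometry varies. This construction powers the package's mechanism
experiment: with identical vessel masks across samples, a vessel-only
conditioned generator receives literally the same input for every sample
and therefore cannot produce sample-specific disc regions — its best
disc-region L1 is that of a constant predictor — while MCML conditioning
sees the disc and cup masks and can place the bright regions correctly.
The acceptance suite runs exactly this comparison.

What the phantom does *not* emulate: real texture and color statistics,
artery/vein distinction, pathology (exudates, hemorrhages), camera
optics, or inter-device variation. Passing tests on phantoms therefore
demonstrates that the conditioning, models, objectives and training
machinery behave as specified — not that the trained models produce
clinically realistic images.

## Metrics

PSNR is `10·log10(data_range² / MSE)` pooled over pixels and channels;
identical images yield an infinite value, reported as a sentinel and
excluded from directory means with a warning rather than silently capped.
SSIM uses the canonical settings — 11×11 Gaussian window, σ = 1.5,
k₁ = 0.01, k₂ = 0.03, data range 255 — computed over valid windows only,
per channel and averaged (a grayscale mode is available; color is the
default). Region-restricted SSIM crops to the ROI bounding box and
weights each window by the ROI value at its center, which reduces exactly
to plain SSIM of the cropped rectangle for rectangular ROIs — the
identity the tests exploit as an oracle. Both metrics are checked against
independent brute-force per-window/per-pixel implementations to 10⁻⁶.

## Problem sizes

The test and acceptance experiments run at sizes chosen to keep the full
suite in the minutes range on one CPU core while preserving the
qualitative regimes of interest: 32 px images and width-4 networks for
unit-level checks, 64 px images and width-8 residual U-nets for the
overfit run (one pair, 300 iterations), the conditioning-mechanism
comparison (8 shared-vessel samples, 15 epochs, seeds 0–2) and the
end-to-end demo (8 samples, 3 epochs). These sizes are the package's own
fixture scale; the architectures themselves accept 256 px and larger
inputs, and the shape contracts are tested up to 256 px.

## Known limitations

* Batch sizes above 1 are supported by gradient accumulation, but
  normalization statistics remain per-sample.
* The engine is CPU-only and single-threaded beyond BLAS; wall time, not
  memory, bounds feasible resolutions (minutes per hundred iterations at
  64 px, width 8).
* Checkpoints are R serializations (RDS), not portable across packages or
  major format revisions; the format string is versioned for that reason.
* Adversarial training at these tiny scales is noisy; the package asserts
  trends (L1 decrease, mechanism ordering) rather than converged image
  quality.
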