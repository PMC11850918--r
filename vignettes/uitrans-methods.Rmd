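---
title: "Restoring low-dose light-sheet volumes with a dual-branch CNN-transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoring low-dose light-sheet volumes with a dual-branch CNN-transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Light-sheet fluorescence microscopy (LSFM) of beating embryonic hearts is
caught between three pressures: imaging speed (a cardiac cycle is a few
hundred milliseconds), light dose (phototoxicity and bleaching limit total
exposure), and image quality. Economical acquisitions — short exposures at
low laser power with plain full-frame detection — suffer two coupled
degradations: photon-limited noise, and a long-range *scattering haze*, the
signal-correlated background that tissue scattering spreads across the
field of view and that no increase in exposure removes. Confocal
line-scanning LSFM (synchronizing the camera's rolling shutter with a
scanned excitation line) rejects most of the scattered light and, at high
power and long exposure, yields clean volumes — but at roughly three
orders of magnitude more light dose and 30x the acquisition time.

This package implements the restoration approach built on that asymmetry:
acquire *pairs* of the same fixed specimen with both protocols, train a
volumetric network to map the economical acquisition to the confocal
high-dose one, and then apply the trained network to economical
acquisitions alone — including rapid in vivo time series for which the
high-quality protocol is physically impossible. Because no public datasets
accompany the original acquisitions, the package ships a synthetic
degradation simulator that reproduces the relevant physics, so the entire
workflow is exercisable and testable end to end on generated data.

## The network

`uitrans()` fits a U-type encoder-decoder whose encoder runs two branches
in parallel at every one of its (default 3) stages:

* a **convolutional branch** — a double 3x3x3 convolution block (leaky
  ReLU activations) that extracts local detail; at stage $i$ it emits
  `base_channels * 2^i` channels;
* a **transformer branch** — a block of two parallel multi-headed
  self-attention (MSA) modules, each emitting half the convolutional
  branch's channels so that their concatenation matches it, capturing
  global context that a small convolutional receptive field cannot.

Both branch outputs are down-sampled x2 by strided convolution and
concatenated along channels; the concatenated map is simultaneously the
skip connection for the decoder and the input of both branches of the next
stage. The decoder mirrors the convolutional side: trilinear x2
up-sampling, a channel-reducing convolution, concatenation with the skip,
and a double convolution block, ending in a 1x1x1 projection back to one
channel. The output has exactly the input's shape.

Each MSA module is: interval-extraction tokenization, a linear embedding,
layer norm, multi-head self-attention with a residual connection, a second
layer norm, and a token MLP (GELU) with a second residual, followed by a
linear projection and exact re-assembly to the 3D layout.

### Interval-extraction tokenization

Tokens are built by *strided sub-sampling* rather than contiguous
patching: the volume is divided into non-overlapping $s^3$ cells and each
cell contributes one token holding its $s^3 \times C$ strided samples.
Every token therefore sees the whole field of view coarsely — the design
goal being global coverage — and re-assembly after the projection is an
exact inverse rearrangement.

The stride is defined at the deepest stage (`token_stride`, default 2) and
doubles at each shallower stage. This schedule keeps the token-sequence
length **constant across stages**: for a $64^3$ input with 3 stages every
stage attends over $8^3 = 512$ tokens. A uniform stride would instead give
$32^3 = 32768$ tokens at stage 1, whose attention matrix alone needs
gigabytes — the per-stage schedule is what makes full-resolution attention
affordable at volumetric scale, and it yields the natural divisibility
requirement (input dims divisible by $2^{n_\mathrm{stages}}$ for the
default stride).

### Channel bookkeeping

With both branches enabled the stage widths follow a single table
(`build_uitrans(...)$schedule`): stage $i$ takes `width[i-1]` channels in
(1 for the first stage), each branch emits $C_i =$ `base_channels`$\cdot
2^i$, and the skip/next-stage width is $2 C_i$. With a branch disabled
(the ablation toggles `conv_branch` / `transformer_branch`) the width is
$C_i$, so a conv-only model bottoms out at `base_channels`$\cdot
2^{n}$ channels — the classic U-Net schedule. A standalone
`transformer_block()` defaults to doubling its input channels, matching
the double-convolution block it runs alongside.

### Things the architecture deliberately leaves out

No positional encoding is used by default: tokens already carry their
cell's spatial samples, and the restoration task is translation-covariant;
a learned embedding is available behind `pos_embedding = TRUE` for
experimentation (it ties the model to one input size). Down-sampling is by
strided convolution (avoids pooling aliasing), up-sampling by trilinear
interpolation plus convolution (avoids checkerboard artifacts). The base
width, head count, embedding multiple and MLP ratio are engineering
choices exposed in `uitrans_config()`; the two twin MSA modules are
identical in structure with independent parameters.

## The training objective

The loss is the weighted sum
$$ L_\mathrm{total} = L_\mathrm{MAE} + \lambda\, L_\mathrm{perc}, \qquad
   \lambda = 0.01, $$
with $L_\mathrm{MAE}$ the volumetric mean absolute error between the
network output and the ground truth, and $L_\mathrm{perc}$ a perceptual
loss computed on 2D z-slices (the x-y planes) and averaged per volume:
slices are replicated to three channels, passed through a *frozen* 2D
VGG-style convolutional pyramid, and compared by mean squared error of the
activations at the configured levels.

The perceptual extractor is by default a fixed, seeded, randomly
initialized network. Random frozen features preserve the loss's role —
penalizing structural, multi-voxel discrepancies that a pointwise MAE
treats as diffuse — while keeping the package fully deterministic and
self-contained; `loss_config(extractor_weights = ...)` accepts externally
supplied pretrained weights for users who want a classic pretrained-VGG
perceptual loss. Which feature levels and which distance enter the loss
are configurable (`perceptual_layers`; MSE is the default distance). The
extractor's parameters are verified bit-identical before and after every
training run.

Optimization is ADAM ($\beta_1 = 0.9$, $\beta_2 = 0.999$) with a constant
learning rate on a seeded 9:1 train/validation split. Before training,
every volume is percentile-normalized (0.1th percentile to 0, 99.9th to 1,
clipped): robust scaling keeps haze offsets and hot voxels from
compressing the dynamic range, and makes input and ground-truth arms
commensurable.

## The degradation simulator

`make_training_pair()` applies a three-step forward model to a shared
phantom, once per arm:

1. **PSF blur** — separable anisotropic Gaussian, defaults matching a
   0.98 um lateral / 4 um axial FWHM detection path (sigma = FWHM/2.355)
   at 0.325 um/voxel. Boundaries are handled by half-sample reflection,
   which conserves interior flux to within 1%.
2. **Scattering haze** — `v + rejection * strength * (v ⊛ K) + offset`,
   with `K` a normalized Gaussian far wider than the PSF (default 10 um).
   An additive, signal-correlated veil is the simplest model that
   reproduces the two facts that matter for restoration: haze scales with
   the specimen's own fluorescence, and line-confocal detection suppresses
   it by a multiplicative rejection factor (1 = conventional LSFM, 0 =
   ideal rejection). Haze is depth-independent here; no attempt is made at
   physically rigorous light transport or tissue-calibrated parameters.
3. **Photon noise** — `Poisson(gain * v)/gain + N(0, read_sigma)`, the
   standard sCMOS shot/read model; `photon_gain` is the light-dose knob.

The preset arms mirror the acquisition protocols: the *economy* input arm
(`lsfm_economy_params()`) uses full haze (rejection 1), ~8 expected
photons at unit intensity, visible read noise and background; the
*quality* ground-truth arm (`lsfm_quality_params()`) keeps the same optics
but rejects 97% of the haze and collects 3000x the photons — the same
dose ratio as the real protocols. Under these defaults the input arm sits
around 0 dB masked SNR and the ground truth near 19 dB, bracketing the
SNR regime the method targets.

The phantom itself (`generate_heart_phantom()`) is two overlapping
ellipsoidal shells — an "atrium" and a "ventricle" with thin Gaussian
walls, emulating the slender myocardial layer — modulated by a seeded
smooth multiplicative speckle so that cell-scale detail exists for
detail-preservation checks. `deform_beating()` turns a phantom into an
exactly periodic 4D sequence by smooth radial dilation about the volume
center.

**What passing on synthetic data does and does not show.** The simulator
reproduces the degradation *structure* (blur anisotropy, signal-correlated
haze, photon statistics, dose ratios) but not zebrafish tissue optics:
scattering parameters are not calibrated, haze has no depth dependence,
and phantoms lack vascular/trabecular morphology. Property-based results
(restoration improves SNR/NRMSE/Pearson on held-out synthetic volumes)
therefore validate the implementation and the training loop, not parity
with the in vivo figures of any particular instrument.

## Numerical and design choices

* **Determinism.** Every stochastic step (phantom texture, noise draws,
  splits, crop corners, data order, initialization) is a pure function of
  explicit seeds; the global RNG state is saved and restored around each
  draw. Identical seeds give bit-identical models.
* **Initialization.** Kaiming-uniform for convolutions, truncated normal
  (sd 0.02) for attention/MLP/embedding weights — the standard pairing for
  hybrid CNN/transformer stacks.
* **Learning rate.** The desk-scale schedule uses 1e-3; at 2e-3 this
  architecture diverges on 32^3 pairs, while 1e-4 (the conservative
  default in `train_config()`) is stable but needs several times more
  epochs. The full acquisition-scale regime (256^3 crops, hundreds of
  pairs) is out of desk reach, so only property-based training claims are
  made.
* **Desk-scale preset.** `uitrans_config_desk()` (base width 8) with
  40 simulated pairs of 32^3 voxels, 9:1 split, 4 epochs (144 steps):
  a full simulate-train-evaluate cycle in minutes on one CPU core, chosen
  as the smallest configuration at which restoration quality margins are
  comfortable. `scripts/acceptance.R` re-runs exactly this pipeline.
* **Registration.** Integer-voxel exhaustive search (joint over the three
  axes) maximizing overlap-only Pearson correlation; ties resolve to the
  smallest, then lexicographically first shift. A x2 pooled prescan with
  +/-2 refinement engages above `max_shift = 8`. Whether the original
  protocol searched axes jointly or sequentially is ambiguous
  ("in all 3 directions"); both are available (`axis_wise`), joint search
  is the default since it cannot be trapped by axis-separable maxima.
* **Metrics.** SNR is `10 log10((mu_fg - mu_bg)^2 / sigma_bg^2)` over
  Otsu masks of the ground truth (the cited sources print no formula; an
  explicit in-package definition keeps every reported number reproducible,
  and GT-derived masks make input/restored/GT comparable). Contrast
  enhancement is the ratio of Michelson contrasts against the input.
  NRMSE normalizes by the reference range; PSNR caps at 120 dB at
  identity; SSIM uses the Wang et al. conventions (Gaussian window sigma
  1.5, K1 = 0.01, K2 = 0.03, population covariance, border strip cropped)
  and matches reference 2D implementations to ~1e-12 on a single slice.
* **Degenerate inputs.** Constant volumes: registration and
  Pearson/SNR/NRMSE raise errors (no-signal); normalization returns 0.5
  with a warning. Negative intensities are clamped before Poisson draws
  (with a warning). Equal-mean masks floor SNR at -120 dB rather than
  returning -Inf.
* **4D synchronization.** The synchronization method of the original
  acquisition chain is external to the text; the realization here is the
  minimal faithful one — per-slice phase offsets chained pairwise by
  circular cross-correlation of high-variance-ROI intensity traces, phase
  bins filled by nearest-frame selection — and is validated by parameter
  recovery on simulated beating phantoms (period to +/-1 frame; offsets
  to +/-1 frame on >= 95% of slices, modulo the global phase gauge, which
  is unidentifiable by construction).
* **Tiled inference.** Cosine-ramp (Hann) tile windows accumulated and
  normalized to an exact partition of unity; volumes smaller than a tile
  are reflect-padded and cropped back. Because attention is global, tiled
  and whole-volume restoration agree only approximately near tile seams;
  the package applies restoration per volume (never per 2D frame) and
  exposes the overlap as a dial.

## Limitations

Training at the original scale (256^3 crops, pretrained-VGG perceptual
features, GPU epochs) is explicitly out of scope; the package claims
correctness and desk-scale effectiveness, not benchmark parity. The haze
model is a stand-in; its parameters are not calibrated to any tissue. No
multi-channel input, no 2D variant, no mixed precision, and no baseline
re-implementations (CARE/RCAN/BM4D/NLM) are provided.
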