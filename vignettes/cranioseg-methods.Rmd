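---
title: "Segmenting craniopharyngioma on coronal T1CE MRI: models, losses, metrics"
author: "cranioseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting craniopharyngioma on coronal T1CE MRI: models, losses, metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Craniopharyngiomas are benign sellar/suprasellar tumors whose appearance on
contrast-enhanced T1 (T1CE) MRI is notoriously heterogeneous: predominantly
cystic, predominantly solid, or mixed. The cyst wall enhances brightly while
the cyst fluid stays dark — darker than surrounding brain — and the internal
carotid arteries run immediately lateral to the tumor as bright tubular
structures that must *not* be included in the tumor outline. A plain U-Net
segments the bright solid component and the enhancing rim well but tends to
miss the dark cyst interior: false negatives dominate its error.

`cranioseg` implements a slice-wise segmentation pipeline addressing exactly
this failure mode with two modifications to the classic U-Net:

1. a **non-local self-attention block** at the bottleneck, so that rim pixels
   can inform the labelling of the enclosed dark interior across long spatial
   ranges, and
2. a **compound Tversky/cross-entropy objective**,
   `L = 0.5 L_Tversky + 0.5 L_CE` with `alpha = 0.1`, `beta = 0.9`, weighting
   false negatives nine times harder than false positives.

## Network

The network is a 2D encoder–decoder applied to coronal sections. Each
resolution level applies two 3×3 convolutions, each followed by instance
normalization and ReLU; 2×2 max pooling halves the resolution on the way
down, and a 2×2 up-convolution (transposed convolution, stride 2, also
norm + ReLU) doubles it on the way up, followed by concatenation with the
matching encoder feature map and two more conv–norm–ReLU layers. A 1×1
convolution with a sigmoid produces the per-pixel foreground probability.
The full-scale configuration is depth 4 with 64 base filters on 256×256
inputs; depth and width are configurable so the identical architecture runs
at desk scale (below).

Two conventions deserve a note, since the level of architectural detail that
matters here (normalization, exact upsampling operator, initialization) is
exactly the part that published descriptions usually leave open:

* **Instance normalization.** Each (channel, sample) plane is normalized
  over its pixels with a learned affine pair. Without any normalization the
  plain conv stack's activation scale drifts during optimization, the
  sigmoid head saturates, and short training schedules stall; instance norm
  is the common choice in medical image segmentation because it is
  batch-size independent and stateless (evaluation is deterministic, no
  running statistics).
* **Weight initialization** is uniform ±1/√fan_in for weights and biases,
  the conventional convolution default.

### The non-local block

At the bottleneck (lowest resolution, `C` channels), one embedded-Gaussian
non-local block computes, for each spatial position `i` of the flattened
feature map `x`,

y_i = Σ_j softmax_j( θ(x_i)ᵀ φ(x_j) ) · g(x_j),   z_i = W_z y_i + x_i

where θ, φ, g are 1×1 convolutions to `C/2` channels and `W_z` projects back
to `C` channels. The attention weights at each position form a probability
distribution over all positions (rows sum to 1). `W_z` is zero-initialized,
so a freshly inserted block is exactly the identity and the modified network
starts from the classic network's function class — this also gives a sharp,
testable contract (`nonlocal_forward` equals its input at initialization,
and a brute-force double-loop attention computation must match the module on
a 2×2 map). A dot-product variant (normalized by the number of positions) is
available behind a flag. Exactly one block is inserted, at the bottleneck
only.

## Loss

The soft Tversky index of probabilities `p` against binary targets `g` is

TI = (Σ p·g + s) / (Σ p·g + α Σ p(1−g) + β Σ (1−p)g + s)

with smoothing `s = 1`; the loss is `1 − TI`. With `α = β = 0.5` it reduces
exactly to the soft Dice coefficient, which the test suite asserts to 1e−9.
Cross-entropy is the binary form with probabilities clamped at 1e−7.

Two numerical choices matter in practice:

* **Per-section Tversky.** The Tversky term is computed per section and
  averaged over the batch (`per_image = TRUE`, flag-switchable to pooled).
  Pooling all pixels of a batch dilutes the foreground gradient whenever
  most sections carry little or no tumor — at desk scale the pooled form
  fails to learn the foreground at all, which is easy to verify by trying to
  overfit two cases.
* **Logit-space gradients.** The training loop propagates
  `∂L/∂logits` directly; the cross-entropy part fuses with the sigmoid to
  `(p − g)/N`, which stays finite and informative when the sigmoid
  saturates. Chaining `∂L/∂p · p(1−p)` instead underflows exactly when the
  network is confidently wrong, freezing training. Every backward path is
  verified against central finite differences in the test suite.

## Preprocessing and augmentation

The preprocessing chain applies four steps: resampling to isotropic
1×1×1 mm (trilinear; masks nearest-neighbour; output grid
`round(size·spacing)` per axis so physical extent is preserved to within
one voxel), in-plane resize to 256×256 (bilinear; masks nearest-neighbour;
in-plane spacing rescaled by `old/new` and recorded honestly), per-volume
min–max normalization to [0,1] (constant volumes map to zero), and
slice-wise CLAHE (clip limit 0.01 normalized, 8×8 tiles — common defaults,
configurable). The default order is resample → resize → normalize → CLAHE:
the network's input size is a hard contract, so the in-plane resize must be
the last geometric step — resampling after resizing would change the slice
size again whenever the in-plane spacing is anisotropic. Whether the
original recipe resized before or after resampling is not recoverable, so
the order is configurable (`preprocess_config(order = ...)`); per-volume
(not per-slice) normalization was chosen as the default.

Augmentation draws, per section and epoch: horizontal flip (p = 0.5),
vertical flip (p = 0.5), rotation uniform in ±10° about the slice center
with zero fill (bilinear for the image, nearest-neighbour re-binarized for
the mask, identical draws for both). Flip probability, center convention and
fill value are conventional choices; the rotation range is part of the
training recipe.

## Synthetic phantoms

Patient data is private, so the package ships a phantom generator producing
image/mask/metadata triples that reproduce the *appearance contrasts* the
method is sensitive to, not anatomy:

* an elliptical "head" of brain-intensity tissue (0.35) with smooth texture
  on a dark background (0.02);
* a tumor as a union of overlapping ellipsoidal lobes (single ellipsoid when
  not lobulated) in a midline suprasellar position, centroid within the
  central third of the head;
* composition-specific rendering — solid: uniform 0.6 with an enhancing
  margin; cystic: a 2-voxel rim at 0.85 enclosing a 0.15 interior (darker
  than brain, the hard case); mixed: rim plus a half-solid/half-cystic
  interior split;
* optionally a bright tube (0.85) hugging the tumor boundary but excluded
  from the mask — the carotid distractor that annotation protocols exclude —
  and a small lateral protrusion included in the mask driving the
  cavernous-sinus subgroup label;
* Gaussian smoothing (0.5 mm) then additive Gaussian noise (σ = 0.03),
  clamped to [0,1].

Cohorts draw composition from the documented mix (34.4% cystic, 17.9%
solid, 47.7% mixed) and feature flags at rates 43% (lobulated), 40.1%
(carotid contact), 54% (sinus invasion); per-case seeds derive from one
master seed. The intensity contrasts are design choices, not estimates — no
quantitative compartment statistics were available to fit. What phantom
results do show: the pipeline's machinery (preprocessing, training dynamics,
metric and statistics plumbing, the relative behaviour of the two networks)
works end to end. What they do not show: absolute performance on patient
MRI, robustness to real acquisition artefacts, anatomy-dependent failure
modes.

`domain_shift()` emulates an external centre by a gamma transform, extra
noise, and optional re-sampling to thicker slices; masks change only through
re-sampling.

## Metrics

All metrics are computed per case on the full 3D stack, never averaged over
slices. With voxelwise confusion counts (TP, FP, FN, TN):
DSC = 2TP/(2TP+FP+FN), Jaccard = TP/(TP+FP+FN) (= DSC/(2−DSC)),
TPR = TP/(TP+FN), FPR = FP/(FP+TN). The FPR denominator is every non-tumor
voxel of the volume, which is why whole-volume FPRs are printed as 0.000.

Surface distances: boundary voxels are foreground voxels with at least one
background 6-neighbour (the image border counts as background); distances
are Euclidean in mm using the voxel spacing; the 95HD is the 95th percentile
(linear interpolation) of the *pooled* union of both directed distance sets
— the dominant convention in medical-imaging toolkits; max-of-directed
percentiles is available by flag. Conventions for degenerate inputs: with
both masks empty DSC = Jaccard = 1 and FPR = 0; TPR is undefined (NA) for
an empty reference; 95HD is undefined when either mask is empty. NA, never
a sentinel value, so means cannot be silently corrupted. Volume is
`count × voxel volume / 1000` mL.

## Statistics

Subgroup analysis mirrors the metric-by-feature grid: each of DSC, Jaccard,
TPR, FPR and 95HD is tested across composition (3 groups) and the three
boolean features (2 groups) by classic equal-variance one-way ANOVA; groups
with fewer than two usable cases make the row "untestable" rather than an
error, NA metric values are dropped with a reported count, and p-values are
reported raw (no multiplicity correction), mirroring how such grids are
conventionally reported. Volume agreement uses ICC(2,1) — two-way
random-effects, absolute agreement, single measurement — with an F-based
95% CI; absolute agreement is the standard for method comparison on
continuous volumes, and the variant is flag-documented since "ICC" alone
underdetermines it. Bland–Altman bias and limits of agreement use the n−1
standard deviation and ±1.96.

## The desk profile and reproducibility

`desk_profile()` pins the scaled-down study conditions used by the test
suite and the acceptance script: 64×64 sections, depth 3, 8 base filters,
batch 8, Adam at 3e−3, ≤40 epochs (15 in the shipped runs), 30-case cohorts
of 64×64×12 phantoms with lobe semi-axes 3–8 mm — one quarter of the
full-scale 8–25 mm default, matching the 4× spatial downscale. The
learning rate belongs to the profile: the full-scale recipe (1e−5, 300
epochs) is far too slow a schedule for 15–40 epochs at desk scale. On one
CPU a desk training run takes a few minutes; a 30-case run reaches
tuning-set mean DSC ≈ 0.9 within ~12 epochs.

Everything stochastic — phantom rendering, cohort draws, splits, weight
initialization, batch order, augmentation — is a deterministic function of
one integer seed, and the random stream is restored afterwards
(`with_seed`), so library calls never perturb a caller's RNG state.

Training keeps background-only sections (real coronal stacks contain them;
`keep_empty_slices = FALSE` drops them). Checkpoint selection takes the
best tuning-set mean DSC, with final-epoch weights kept alongside. The
8:2 split takes `floor((1−ratio)·N)` test cases — with 264 cases,
ratio 0.8 and a 10-case tuning set this is exactly 202/10/52.

## Known limitations

* At desk scale the modified and classic networks perform equivalently:
  across training seeds, both reach mean DSC ≈ 0.9 on held-out phantoms and
  the modified-minus-classic DSC difference fluctuates around zero (±0.02).
  The 64×64 phantoms with 3–8 mm tumors are easy enough that the non-local
  block's long-range-context advantage — aimed at large dark cyst interiors —
  has no headroom to appear; a fixed-seed ordering test of the two
  architectures is therefore a coin flip at this scale, and the paired
  comparison (`compare_models`) should be read accordingly.
* 2D slice-wise only; no 3D convolutional variant.
* Single-sequence (T1CE) input; no multi-modal channels.
* The phantom generator makes no claim to anatomical or MR-physics realism
  (no k-space, no coil or bias field model, no calcifications).
* The DICOM reader covers uncompressed little-endian single-frame series
  only; NIfTI-1 is the canonical interchange format.
* Constant learning rate; no schedule or hyperparameter search.
* CPU-only training; the full-scale 256×256 / depth-4 / 300-epoch recipe is
  expressible in configuration but not practical without an accelerator.
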