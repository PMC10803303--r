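---
title: "Models, phantoms and numerical choices in mlnet3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, phantoms and numerical choices in mlnet3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mlnet3d` re-implements, at desk scale and on synthetic data, a two-stage
pipeline for baseline rectal-cancer MRI: automated tumour segmentation with a
deep-supervised 3D U-Net, followed by classification of EMVI status and
prediction of complete response by a skip-less 3D ResNet10 backbone into
which the segmenter's multi-level feature maps are injected by concatenation
("MLNet"). This vignette records the model assumptions, the phantom world the
package tests itself on, and the numerical and design choices a maintainer
would want written down. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The segmenter and deep supervision

The segmenter is a miniature stand-in for a self-configuring U-Net framework:
an explicit `unet_config` replaces automatic configuration (dataset
fingerprinting and plan generation are out of scope), and preprocessing is
fixed to per-volume, per-channel z-scoring. The network has `S = 4`
resolution stages, one 3×3×3 convolution per encoder stage with stride-2
convolutions between stages, channel widths doubling from `base_channels`
(default 8: 8/16/32/64), and a decoder that trilinearly upsamples, concatenates
the encoder skip, and convolves once per stage. Every convolution is followed
by instance normalisation and ReLU; normalisation is required for stable
CPU-scale training and degrades to a per-channel affine map on single-voxel
grids (normalising one voxel would annihilate it).

Deep supervision: each decoder stage (the bottleneck acting as the coarsest
stage) carries a 1×1×1 sigmoid head supervised against the ground-truth mask
*trilinearly* downsampled to that stage's grid — trilinear rather than
nearest-neighbour is deliberate (it matches how self-configuring U-Net
frameworks build their deep-supervision targets), so the coarse targets are
soft values in [0, 1]. The per-stage loss is soft-Dice
plus voxel-wise cross-entropy (the standard composite of such frameworks),
and the total loss is the weighted sum over stages with
weights proportional to `2^(1-s)`, normalised — finest stage weighted most,
the usual deep-supervision convention, exposed in the config because the
weights are a genuinely free choice.

The **feature pyramid** injected into the classifiers is taken from the
decoder path (the activations feeding the deep-supervision heads), stage 1
finest. Encoder activations would be the other defensible tap; the decoder
was chosen because it is the deep-supervision path — those are the
activations actually trained against the multi-scale mask targets.

## MLNet and the ablation family

The classification backbone is a 10-weight-layer 3D ResNet: stem convolution
(stride 2), four two-convolution blocks with widths 8/16/32/64 (stride-2
first convolution in blocks 2–4), a pooled head and one logistic unit. The
head concatenates global average and global max pooling: the EMVI-like
signal occupies a fraction of a percent of the volume, and average pooling
alone dilutes such sparse presence signals below what is learnable at desk
scale (canonical ResNet10 pools by average only; this is a deliberate,
tested deviation).
The `plain_resnet10` variant keeps identity/projection shortcuts. The
injecting variants (`mlnet`, `stage1`..`stage4`) *remove* the shortcut and
concatenate the stage-s feature volume (the decoder activations plus that stage's
predicted foreground probability as a final channel) — trilinearly resampled
to the block-s input resolution, without channel reduction, activation
channels standardised per case while the probability channel keeps its
calibration — to the input of block s, so the
finest features reach the earliest, highest-resolution block. Two open
wiring questions were settled as: concatenation at the *input* of the block
(before its first convolution), and raw concatenation without a 1×1×1
reducing convolution; nothing beyond concatenation at the matching level is
externally constrained, so the simplest wiring was chosen. The original image is always an input
through the stem; injection changes channel counts only, never spatial
dimensions.

Training: class-weighted binary cross-entropy with positive-class weight
defaulting to the training split's negative/positive ratio (the weighting scheme is otherwise unconstrained; the ratio is the
standard choice for the ~30% CR prevalence); Adam at learning rate 1e-4
with batch size 4 (implemented as gradient accumulation); the whole step
wrapped in sharpness-aware minimisation with `rho = 0.05` (the optimiser's
usual default). Early stopping uses patience 10 on the
internal-validation loss with an epoch cap of 100, and the checkpoint returned is the best
validation-loss epoch. The validation loss uses the training split's class
weight, so checkpoint selection optimises the same objective being trained.

## The phantom world

Real data being private, the package generates its own: 3D two-channel
volumes (default 32³ voxels at 2 mm) containing one tumour, across 9 centres
with per-centre multiplicative gain (0.85–1.15), smooth bias fields (up to
0.08) and substantial Gaussian noise (σ 0.18–0.30 per centre) — the noise
level is a deliberate part of the world: it emulates the pronounced
quality variation of a long-running multi-scanner cohort, and it is what
separates the two routes to the EMVI signal (below).
Label prevalences default to the cohort table's 60% EMVI+ and 28% CR.
Clinical covariates are sampled to the table's marginals (age ~N(65, 11)
clipped to 25–87; 35% female; cT 7/81/12%; cN 13/24/63%) and are
*independent of the labels* — the phantom plants image signal, not clinical
signal, so the logistic-regression baseline is expected to sit at chance.

The tumour is an ellipsoid with semi-axes drawn from 8–14 mm and a smooth
multiplicative boundary perturbation (relative amplitude 0.08). The two task
signals are deliberately placed at different spatial scales, which is what
makes the stage-wise ablation pattern testable:

- **EMVI-like (fine)**: three tubular protrusions (11 mm long, 3.2 mm
  radius, within mesorectal vessel calibre) extend beyond the tumour body at
  tumour-level intensity — vessel-invading tumour tissue reads as bright as
  the tumour itself on high-b DWI. Because the tubes are thin and the noise
  floor is high, per-voxel brightness is not a usable shortcut: detecting
  them requires spatial integration, which the mask-supervised segmenter
  learns (its ground truth includes the protrusions) and a from-scratch
  classifier on the raw image does not acquire within a desk-scale budget.
  The segmenter's finest-stage features therefore carry a denoised tube
  marker that the injecting classifiers can read, while the coarse stage-4
  grid cannot resolve it — the mechanism behind the stage-wise ablation
  pattern. An optional `distractor_vessels` knob can additionally plant
  detached tumour-bright tubes in every case (excluded from the mask) to
  remove even the "some tube exists" shortcut; it is off by default because
  the attachment discrimination it demands is not learnable within the
  desk-scale training budget.
- **CR-like (coarse)**: responders (CR = 1) have smaller (×0.78) and more
  homogeneous tumours; non-responders carry a low-frequency internal texture
  (amplitude 0.6).

The T2W-like channel is synthesised at half the in-plane spacing with
inverted contrast and resampled onto the DWI grid, mirroring the real
preprocessing in which T2W is brought into the DWI domain. Masks resample by
nearest neighbour; coordinates are 0-based with world = origin + index ·
spacing.

What the phantoms do *not* emulate: MR physics (no k-space, b-values or
partial-volume model), anatomy beyond one lesion, inter-reader label noise,
and realistic lesion-morphology statistics (none are available for the
private cohort, so phantom parameters are stated choices, not
calibrations). A green test therefore establishes that the pipeline's
machinery — losses, wiring, splits, thresholds, statistics — behaves as
specified on a controllable world, not that the clinical performance figures
transfer.

## Statistics

All formula-level statistics live in one module. Dice uses the convention
Dice(∅, ∅) = 1 and Dice(pred = ∅, gt ≠ ∅) = 0, matching the reporting of
failed segmentations as "Dice = 0.00". AUC is the rank-sum estimator with
midranks for ties (which makes it exactly the Mann–Whitney estimator); the
ROC staircase integrates to the same value to 1e-9 by construction and is
tested as such. The classification rule is `score ≥ threshold ⇒ positive`
everywhere. The Youden operating point scans the unique observed scores,
breaks ties toward the smallest threshold, and is transferred bit-identically
to external sets. Bootstrap CIs are percentile, case-level and
non-stratified with invalid (single-class) resamples redrawn and counted —
the CI variant and stratification are otherwise unconstrained, so the
simplest variant was chosen and is verified by a coverage simulation (true
AUC 0.8, n = 100: 90–99% coverage). Tests are two-sided at α = 0.05;
Kruskal–Wallis and Mann–Whitney wrap the standard tie-corrected R
implementations (exact enumeration for small untied samples).

## Explainability

Grad-CAM++ is generalised to three spatial axes: per-channel weights are
`w_k = Σ α_k · relu(∂y/∂A_k)` with the α ratio's denominator summing
`A · g³` over all three axes; the weighted activation sum is clamped to
non-negative, trilinearly upsampled to the input grid and max-normalised.
One numerical choice: gradients are divided by their global absolute maximum
before the α computation. The textbook ratio is not invariant to a positive
rescaling of the logits (the third-order term scales differently from the
second-order one); the normalisation makes the attention map exactly
invariant to logit scaling, at the cost of reweighting the α denominator by
that same constant. The default target layer is the last injected block
(block 4 for the plain variant), configurable per call. The peri-tumoural
overlap surrogate takes the top-decile positive-attention voxels and reports
the fraction inside the mask dilated by 2 voxels.

## Desk-scale budgets

The acceptance protocol trains on one CPU: the segmentation replication uses
40 phantoms at 32³ for 14 epochs (minutes, reaching held-out Dice well above
the 0.7 bar), and the injection ablation uses a 200-case cohort with a 4/2/3
centre-wise split, classifier runs at learning rate 1e-3 with base width 4,
an epoch cap of 30 and patience 20, and 4 of the 6 variants. The
protocol-scale defaults (lr 1e-4, width 8, patience 10) remain the config
defaults; at desk scale lr 1e-4 converges too slowly, and patience 10
measured against a 44-case validation loss fires during the optimiser's
warm-up plateau and returns pre-learning checkpoints. Training further uses
random axis-flip augmentation and a small decoupled weight decay (1e-4),
without which the 90-case training split is memorised outright. Bootstrap replications are
reduced from 10,000 to ~1,000 in tests. These reductions change runtimes,
not the protocol structure: splits, losses, SAM, threshold transfer and
metrics are identical to the full-scale configuration.

## Known limitations

Single-volume (batch-accumulated) instance-norm training rather than true
batch statistics; no test-time augmentation, connected-component
post-processing or region-based training; the DWI+T2W arm shares the DWI
arm's architecture with `input_channels = 2` and is exercised functionally
rather than at protocol scale; Grad-CAM++ maps from the coarsest block are
necessarily low-resolution and their overlap statistics should be read
qualitatively.
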