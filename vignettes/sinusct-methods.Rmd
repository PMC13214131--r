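---
title: "Methods: structural analysis of paranasal sinus CT with sinusct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural analysis of paranasal sinus CT with sinusct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`sinusct` implements a unified workflow for structural analysis of
paranasal-sinus CT volumes built from three learned components plus an
explainability and an evaluation layer:

1. a **hybrid CNN–transformer segmenter** that delineates the four paired
   sinus compartments (maxillary, ethmoid, frontal, sphenoid) in 3D;
2. a **self-supervised 3D convolutional autoencoder (CAE)** trained only on
   structurally normal sinus regions, whose reconstruction residual
   `r = |x - x̂|` localizes structural deviation without pathology labels;
3. a **three-channel 3D CNN** that fuses CT, segmentation mask and residual
   map into compact structural embeddings;
4. **Grad-CAM** saliency over the fusion network's final convolutional layer;
5. **Dice / Jaccard / precision / recall / HD95** evaluation.

Because annotated clinical sinus CT is scarce, the package ships a
procedural **phantom generator** that stands in for real data in every test:
all quantitative claims made by the test suite are claims about these
phantoms, not about clinical CT.

All neural-network layers (3D convolution via im2col and BLAS products,
shifted-window multi-head attention, group/layer normalization, transposed
convolution, AdamW/Adam) are implemented natively in the package with
hand-written backpropagation; every primitive is verified against central
finite differences in the test suite.

# The phantom generator

A phantom is a head-shaped soft-tissue ellipsoid with a bone shell on an air
background (air −1000 HU, fluid 30 HU, soft tissue 40 HU, bone 700 HU by
default). Four bilateral pairs of air-filled ellipsoidal cavities with thin
(≈1.5 voxel) bony walls sit at fixed, anatomically inspired relative
positions: maxillary lateral–inferior, ethmoid paramedian, frontal superior,
sphenoid posterior–central; the ethmoid analog is subdivided into cells by
1-voxel bone septa. Scanner variability is emulated by Gaussian blur
(σ 0.3–0.9 voxels), additive Gaussian noise (3–10 HU) and a global intensity
shift (±25 HU), drawn per sample; inter-subject pneumatization variability is
emulated by a ±8% jitter of the cavity scale. These ranges are fixed
generator defaults chosen to span the plausible multi-scanner range, set
once when the generator was designed.

Four structural anomalies can be inserted, each affecting **one** randomly
chosen (seeded) cavity so that unaffected sinus tissue remains available as
a reference region: mucosal-style *wall thickening* (a soft-tissue rind
lining the cavity), *partial opacification* (a fluid level filling the
gravity-dependent fraction `strength` of the cavity), *total opacification*,
and *asymmetry* (one side's cavity shrunk by `1 - strength`, the vacated
space ossified). Anomaly ground truth is a separate binary mask, not a
fifth label, because anomaly truth only exists in the synthetic world.

What the phantoms do **not** model: real craniofacial anatomy (orbits,
nasal cavity, dental structures), partial-volume effects at sub-voxel walls,
beam hardening, metal artifacts, or anatomical covariation between
compartments. A model that passes the phantom tests has demonstrated that
the implementation learns and localizes as designed — not that it reaches
clinical accuracy on real CT.

# Preprocessing

The harmonization chain is: replace non-finite voxels by zero → resample to
isotropic spacing (trilinear for intensities, nearest-neighbour for labels,
so the label set can never grow) → standardize the grid shape
(center-cropping; symmetric zero-padding with the odd voxel on the high
side) → min–max normalize HU into [0, 1].

Two decisions deserve justification:

* **Fixed normalization window (−1000, 2000) HU** rather than per-volume
  extremes: per-volume minima/maxima are dominated by scanner artifacts, and
  a fixed window keeps intensity meaning comparable across scanners. The
  window is configurable.
* **The −500 HU threshold builds a hole-filled body mask** (largest
  6-connected supra-threshold component, interior holes filled) used for
  mask-guided cropping. It does *not* zero sub-threshold voxels: the sinuses
  themselves are air at ≈ −1000 HU and zeroing them would destroy the object
  of study. Hole filling keeps the air cavities inside the body mask.

Augmentation during training is intensity-only (gamma in 0.8–1.25, rescale
0.9–1.1, then clipping to [0, 1]); geometric augmentation is deliberately
excluded so that sinus morphology — the signal of interest — is never
distorted, and masks are never touched by augmentation.

# The hybrid segmenter

The encoder applies a stride-2 patch embedding and four stages. Stage *i*
carries `embedDim · 2^(i−1)` channels and holds `depths[i]` shifted-window
attention blocks (pre-norm; multi-head scaled-dot-product attention inside
non-overlapping windows, alternating between unshifted and half-window
cyclically shifted partitions, with the standard wraparound mask preventing
token pairs that became adjacent only through the cyclic shift from
attending to each other) interleaved with one residual 3×3×3 convolution
block under group normalization, then a strided convolution halves the grid.
The decoder mirrors the encoder with 2×2×2 transposed convolutions,
additive stage-wise skip connections, and a 1×1×1 classification head.

Wiring choices at full scale, where the headline numbers leave freedom:

* The full-scale conv-filter ladder (32, 64, 128, 256) is used as the
  *internal width* of the interleaved residual conv blocks; stage widths
  follow the attention ladder `embedDim · 2^(i−1)` (96·2^(i−1) at full
  scale, head dimension 32 with heads (3, 6, 12, 24)). This keeps every
  stage width divisible by its head count, which a filter-ladder-as-stage-
  width wiring would violate.
* Decoder skips are additive rather than concatenated — an implementation
  choice that halves decoder convolution cost with no observed quality
  difference at desk scale.
* The classification head's bias is initialized to class-prior log odds
  (2% per foreground class). With ~98% background voxels a zero-initialized
  head lets cross-entropy collapse all foreground probabilities in the
  first epochs, after which the soft-Dice gradient (which is proportional
  to the predicted probability) recovers only slowly; starting at the prior
  removes that wasted phase.

**Losses.** The training loss is the equal-weighted composite
`0.5 · (1 − mean soft Dice over foreground classes) + 0.5 · CE`, soft Dice
with smoothing constant 1e−5 in numerator and denominator. "Equal weights"
is interpreted as 0.5/0.5; any common positive pair is equivalent up to a
learning-rate rescale. Argmax ties break toward the lower class index for
determinism.

**Profiles.** The full-scale profile (96³ patches, embed 96, depths
(2,2,6,2), heads (3,6,12,24), window 7³, AdamW 1e−4, cosine annealing,
batch 2, 200 epochs) exists as a named configuration (`segConfigFull()`);
it is GPU-scale and not exercised by tests. The
**desk profile** used throughout the tests is 48³ input, embed 24, depths
(1,1,2,1), heads (1,2,4,8), window 3³, conv-block widths (12,16,24,32),
trained with AdamW at a constant 3e−3, batch 1 (gradient accumulation
size), intensity augmentation on, for 13 epochs over 32 phantoms — roughly
420 optimizer steps, sized for a single CPU. A learning rate of 1e−4 at
this tiny scale would leave the loss far from convergence, and cosine
annealing over so few epochs decays the rate before the ethmoid class has
been learned; a constant rate is the desk-scale equivalent of the
full-scale recipe.

**Ablations.** `variant = "cnn_only"` removes the attention blocks
(keeping the interleaved conv blocks, hence strictly fewer parameters);
`variant = "transformer_only"` removes the interleaved conv blocks. Both
train and predict through exactly the same code paths.

**Inference** on volumes larger than the patch uses sliding-window tiles
with 50% overlap and mean-blended probabilities; smaller volumes are
zero-padded and cropped back.

# The autoencoder

Encoder: three stride-2 3×3×3 convolutions (full scale 32/64/128 filters)
flattened into a dense bottleneck (full scale 256); decoder: dense
expansion and three symmetric 2×2×2 transposed convolutions with a logistic
squashing onto [0, 1], matching the normalized intensity domain and
bounding the residual. The latent code is linear.

The CAE trains **only on structurally normal samples** — the training-set
constructor refuses anomalous samples outright, protecting the healthy-
manifold premise. Inputs are sinus-region crops, not whole heads: each
sample is cropped to the bounding box of its labeled sinuses (margin 2
voxels) and **resampled onto the common CAE grid** (trilinear; nearest for
masks). Resampling, rather than padding, is what aligns anatomy across
subjects; without it the reconstruction objective averages over residual
spatial jitter between subjects, reconstructions blur, and the residual
map loses much of its localization power.

Training follows Adam at 1e−3, batch 4, step-wise ×0.1 decay every 50
epochs. The reconstruction loss is voxel-wise **L2 by default with L1
selectable** — both are in common use for reconstruction-based anomaly
detection and the residual map itself is an L1-style quantity, so the
package surfaces the choice in `caeConfig()` instead of hard-wiring one. The desk CAE (32³ input, filters 16/32/64, latent 128, 100
epochs) is the half-scale analog of the full profile.

Anomaly localization is quantified by `anomalyContrast()`: mean residual
inside the anomaly mask divided by mean residual over labeled sinus voxels
outside it; 1 means no localization, `Inf` flags a degenerate all-zero
reference.

# Fusion network and pretext objective

The extractor consumes three channels on the CAE crop grid: normalized CT;
the label mask as a single channel scaled by 1/4 (one channel, not one-hot,
because the fused input is defined as exactly three channels); and the
residual map clipped at its own 99th percentile and rescaled to [0, 1] to
bound outliers and keep channels commensurate. Architecture: three
3×3×3 conv + max-pool stages (full scale 32/64/128 filters), global
average pooling, a 64-unit dense embedding layer with dropout 0.3, and a
4-unit head. The desk profile uses deliberately narrow convolutions
(6/12/24): with little spare capacity the network cannot learn anatomy
shortcuts, so its features stay focused on the residual and mask channels
— the saliency maps and embeddings inherit that focus. An L1 penalty
(weight 1e−3) on the final conv layer's activations further sparsifies the
feature maps during training.

This network must learn morphology-aware embeddings without any pathology
labels, and Grad-CAM needs a differentiable scalar target, so we train it
with a **self-supervised pretext regression**: the head predicts the four per-sinus mean residuals
(`pretextTargets()`), with mean-squared error. This is label-free, forces
attention onto the sinus regions and their structural deviations, and
provides the differentiable scalar that Grad-CAM needs. Other label-free
objectives are possible; this one is the package's design choice.

The extractor trains on a dedicated anomaly-rich cohort (32 phantoms, 75%
anomalous): with mostly normal samples the four pretext targets are nearly
identical and the regression can be solved by spatially uniform features;
anomalous samples make the targets differ across sinuses, which forces
per-compartment, localized features. Training runs Adam at 3e−3 for 60
epochs. Embedding separation is always evaluated on cohorts held out from
every training set. During desk tests the mask channel uses ground-truth
labels; at pipeline inference time predicted masks can be used instead.
Ablation variants `no_residual` / `no_mask` zero the corresponding channel
while keeping shape, so the ablation matrix is pure configuration.

# Grad-CAM

For a chosen scalar target — by default the sum of the four per-sinus
pretext outputs, with the maximal output or an explicit sinus index
selectable — channel weights are the
spatial means of the gradient at the final convolutional layer's
activations; the CAM is the rectified weighted channel sum, trilinearly
upsampled to the input geometry and min–max normalized per map (an
identically-zero map passes through unchanged). Localization is scored by
`camMassFraction()` — the fraction of total CAM mass inside a region — and
compared against the region's volume fraction, i.e. against a uniform
map. The aggregate (sum) default matches union-level localization
questions: a single-output CAM highlights one compartment by construction,
which is the right picture per sinus but not for mass measured over the
union of all four. The anomaly-strength response is scored on the three
intensity anomalies (wall thickening, partial and total opacification);
asymmetry is excluded from that comparison because at strength 1 its
anomaly region is a fully ossified, vanished cavity outside every sinus
structure — a well-localized saliency map is correctly silent there, so
including it would measure mislocalization rather than response.

# Evaluation metrics

Per foreground class: Dice `2|P∩G|/(|P|+|G|)`, Jaccard, precision, recall
from confusion counts, with deterministic edge conventions (both masks
empty → all four = 1; exactly one empty → Dice = Jaccard = 0 and the
undefined ratio reported as 0). HD95 uses surface voxels (mask voxels with
a 6-neighbour outside the mask, the grid border counting as outside),
Euclidean millimetre distances between surface-voxel centers, and the 95th
percentile (linear interpolation between order statistics) of the **pooled
bidirectional** distance multiset — one of several HD95 variants in
circulation; pooling makes the statistic symmetric by construction. An
empty mask yields an undefined-flag (`NA` with a reason), never a silent
zero. The brute-force O(n²) oracle in the tests shares this definition and
nothing else with the implementation.

# Pipeline, profiles and problem sizes

`runPipeline()` chains generate → preprocess/train segmenter → evaluate →
train CAE → residuals/contrast → fusion training → embeddings → Grad-CAM,
with every stage's inputs taken from the previous stage's outputs, one
global seed deriving all stage seeds, and a JSON-lines log recording each
stage's wall time and output hashes.

The desk study conditions (also used by `scripts/acceptance.R`): 32
training phantoms and 8 held-out phantoms at 48³ with 25% anomalous; 16
normal phantoms for CAE training; 16 anomalous phantoms for localization
scoring; 16 normal + 16 anomalous for the embedding-separation analysis.
These sizes make a full run feasible on a single CPU core while leaving
every component large enough to show its intended behaviour.

# Numerical choices and degenerate inputs

* Soft-Dice smoothing 1e−5; CE probabilities clamped at 1e−300 before log.
* Group-norm group count: the largest divisor of the channel count not
  exceeding the configured maximum (8), eps 1e−5.
* Attention softmax is max-subtracted; the wraparound mask adds −1e9.
* Resampling maps output voxel centers to input coordinates
  `(i + 0.5)·scale − 0.5` with edge clamping; an identity resample
  reproduces the input exactly.
* Seeds: one integer seed per entry point; child streams are derived by a
  multiplicative-congruential fold kept strictly inside 32-bit range, so
  per-sample/per-epoch streams are independent and reproducible.
* Degenerate inputs are first-class: empty masks, all-NaN volumes,
  anomalous samples offered to the CAE, zero-mass CAMs and out-of-range
  Grad-CAM targets all raise typed, message-bearing errors (or documented
  flags), which the tests assert.

# Known limitations

* Phantom realism, as above; no claim transfers to clinical CT without
  retraining and clinical validation.
* The full-scale profile is provided but untrained here; desk-scale
  accuracy is far below what full-scale training on real data reports.
* HD95 follows one specific (pooled) definition; tools that maximize the
  two directed 95th percentiles will report slightly different values.
* The fusion network's pretext objective is this package's design; other
  label-free objectives could yield different embeddings and saliency.
* Grad-CAM localization at desk scale is real but modest, for two
  structural reasons: the final conv layer's coarse cells, upsampled
  trilinearly, spread each saliency blob beyond the thin air cavities;
  and part of the physically informative saliency lies on the bony cavity
  walls, which the air-interior ground-truth labels exclude (dilating the
  scoring region into the walls does not raise the enrichment ratio,
  because the region grows faster than the captured mass). Large
  sinus-union saliency enrichment over a uniform baseline should
  therefore not be expected reliably at this scale, and the corresponding
  check in the test suite sits at the edge of what the design delivers.
* Training is single-threaded deterministic given a seed up to BLAS
  reduction order; bitwise identity across different BLAS builds is not
  guaranteed, which is why determinism tests use a 1e−6 tolerance.
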