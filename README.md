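# sinusct

Structural analysis of paranasal-sinus CT volumes in R: anatomical
segmentation, self-supervised anomaly localization, structural embeddings,
and explainability — exercisable end to end on procedurally generated sinus
phantoms.

## Who this is for

Researchers in medical image analysis who want a fully inspectable,
dependency-light reference implementation of a hybrid CNN–transformer
segmentation + reconstruction-residual anomaly-detection workflow for 3D
CT, and who need every numerical claim to be reproducible on a single CPU.
The package contains no GPU code and no external deep-learning framework:
all layers (3D convolution over im2col/BLAS, shifted-window multi-head
self-attention, group/layer normalization, transposed convolution,
AdamW/Adam) are implemented natively with hand-written backpropagation and
are verified against finite differences in the test suite.

## The method

Four paired air-filled cavities — maxillary, ethmoid, frontal and sphenoid
sinuses — are segmented from head CT by a hybrid encoder that interleaves
shifted-window self-attention blocks (window-restricted multi-head
scaled-dot-product attention, alternating unshifted and cyclically shifted
partitions) with residual 3×3×3 convolutions under group normalization,
decoded by transposed convolutions with stage-wise skips. Training
minimizes the equal-weighted composite

```
L = 0.5 · (1 − mean_c softDice_c) + 0.5 · CE
```

A 3D convolutional autoencoder trained **only on structurally normal**
sinus regions learns the healthy morphology manifold; at inference the
residual map `r = |x − x̂|` highlights structural deviation, quantified as
the contrast `mean(r | anomaly) / mean(r | normal sinus)`. A three-channel
3D CNN (CT ⊕ mask ⊕ residual) produces 64-dimensional structural
embeddings via a self-supervised per-sinus mean-residual regression, and
Grad-CAM over its final convolutional layer yields voxel saliency maps.
Segmentation quality is reported as Dice, Jaccard, precision, recall and
the 95th-percentile Hausdorff distance (mm, pooled bidirectional surface
distances).

A procedural phantom generator (head-shaped tissue ellipsoid, four
bilateral cavity pairs with thin bony walls, ethmoid septation,
scanner-style noise/blur/shift jitter, and insertable wall-thickening /
opacification / asymmetry anomalies with ground-truth masks) stands in for
clinical data in all tests.

## Worked example

```r
library(sinusct)

# a phantom with a partially opacified sinus
s <- generatePhantom(phantomSpec(anomaly = "partial_opacification",
                                 anomalyStrength = 0.8, noiseSdHu = 5,
                                 blurSigmaVox = 0.5, seed = 7))
s
#> PhantomSample:
#>   CTVolume 48x48x48 voxels, spacing 1x1x1 mm, HU [-1022, 714.7]
#>   SinusLabels 48x48x48 voxels; foreground voxels: maxillary=1112,
#>   ethmoid=298, frontal=230, sphenoid=256
#>   anomaly: partial_opacification (92 voxels)

# preprocess and score a (here: perfect) segmentation
pp <- preprocessVolume(phantomVolume(s), phantomLabels(s))
ev <- evaluateSegmentation(pp$labels, pp$labels)
ev$per_class[, c("name", "dice", "hd95_mm")]
#>        name dice hd95_mm
#> 1 maxillary    1       0
#> 2   ethmoid    1       0
#> 3   frontal    1       0
#> 4  sphenoid    1       0

# overlap metrics on hand-counted masks: |P| = 4, |G| = 6, |P∩G| = 3
p <- array(0, c(3, 3, 1)); g <- p; p[1:4] <- 1; g[2:7] <- 1
unlist(overlapMetrics(p, g))
#>      dice   jaccard precision    recall
#> 0.6000000 0.4285714 0.7500000 0.5000000
```

The numbers mean: Dice 0.6 = 2·3/(4+6); Jaccard 3/7 (note
J = D/(2−D)); precision 3/4 of predicted voxels are true; recall 3/6 of
true voxels were found. An end-to-end run — cohort generation, segmenter
and autoencoder training, residual contrast, embeddings, Grad-CAM,
evaluation tables and a provenance log — is one call:

```r
res <- runPipeline(runConfig(outDir = "run1", seed = 1))
res$summary$mean_foreground_dice
```

A thin command-line interface with the same stages is installed at
`system.file("scripts", "sinusct", package = "sinusct")`
(`generate-data`, `preprocess`, `train-seg`, `predict`, `train-cae`,
`residual`, `features`, `explain`, `evaluate`, `run-all`; every subcommand
honors `--seed`).

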