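---
title: "Methods: glioma grading from H&E images with molecular fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glioma grading from H&E images with molecular fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`gliopipe` implements a digital-pathology workflow for grading diffuse
gliomas from hematoxylin-and-eosin (H&E) slides together with the four
molecular markers that anchor modern CNS tumor classification: IDH
mutation, ATRX mutation, 1p/19q codeletion, and MGMT promoter
methylation. The pipeline runs in five stages:

1. **ROI selection** — a whole-slide image is thumbnailed, over-segmented
   into superpixels, and the darkest superpixels (highest cellular
   density under H&E) nominate the region of interest.
2. **Stain normalization** — structure-preserving color normalization by
   sparse non-negative stain separation.
3. **Nuclei segmentation** — a classical stain-threshold backend or a
   small trainable encoder–decoder network.
4. **Cellularity** — the area fraction of (optionally dilated) nuclei.
5. **Cascaded grading** — stage 1 (plain CNN) separates high-grade from
   lower-grade glioma; stage 2 (residual network) separates grade II from
   grade III, both fusing image patches with the molecular vector and
   cellularity.

Because full-scale slide archives and GPU training are out of scope for a
desk-scale package, every stage is validated against a seeded synthetic
histology generator with exact ground truth. This vignette records the
models, the tunable parameters, and the design decisions taken where the
problem statement left the design open.

# Synthetic histology generator

The generator is first-class, tested code: it defines the study
conditions under which the package's claims are checked.

**Image model.** Tissue transmits light according to Beer–Lambert:
`I = I0 * exp(-X)` with `I0 = 255` and per-pixel optical density
`X = hv * d_H + ev * d_E`, where `hv` and `ev` are the 3-channel
absorbance vectors of hematoxylin and eosin and `d_H`, `d_E` the stain
densities. Defaults are the widely used Ruifrok reference vectors,
`hv = (0.65, 0.70, 0.29)` and `ev = (0.07, 0.99, 0.11)` (the source
material prints no stain vectors, so the conventional ones are used).
Nuclei are ellipses with semi-major axis 3–5 px and eccentricity up to
0.7, placed by uniform rejection sampling (overlap allowed, as in
tissue); each nucleus draws a hematoxylin density in [0.85, 1.25].
Background receives an eosin density calibrated so its brightest channel
sits at level 210, which keeps the pink background *above* the
optical-density tissue threshold — both stains are then represented among
fitted pixels, making two-stain separation well-posed. A
`stain_perturbation` parameter jitters the stain vectors per image to
emulate scanner and staining variability.

**What it does not emulate:** chromatin texture, nucleoli, mitoses,
necrosis, microvascular proliferation, tissue folds, and out-of-focus
blur. Passing tests therefore demonstrate correctness of the algorithms
under the stated stain model, not clinical performance on real slides.

**Mock slides.** `generate_mock_wsi()` renders a bright glass background
(≈244, above the glass-exclusion threshold of 240) with dark elliptical
tissue blobs (≈110–135) and, optionally, a near-black ink polyline 15 px
wide, disjoint from tissue. The ink is darker than any tissue, so
intensity-ranked ROI selection deterministically prefers it — the
documented failure mode of pen-annotated slides.

**Cohorts.** `generate_cohort()` draws, per case, a nuclei count from a
grade-conditional normal (defaults: means 12 / 21 / 38 with sd 2.5 /
3.5 / 5 on a 64 × 64 ROI), a molecular profile from grade-conditional
priors (e.g. P(IDH MT) = 0.85 / 0.75 / 0.10 for grades II / III / IV,
mirroring the strong depletion of IDH mutations in glioblastoma), and a
histology label (grade IV is always GBM; codeleted LGG cases are mostly
oligodendroglioma). These densities give mean ground-truth cellularities
of roughly 0.12 / 0.21 / 0.36, i.e. the monotone grade–cellularity
relationship the cascade is expected to recover. The 64 × 64 ROI size is
the package's chosen desk-scale study condition; all counts scale with
ROI area.

# ROI selection

Ranking uses the Rec. 709 luma. Over-segmentation is SLIC-style
clustering: k-means over `(row·m/S, col·m/S, R, G, B)` with grid-seeded
centers, `S = sqrt(n_pixels / n_superpixels)` and compactness `m = 10`,
followed by a connectivity pass that splits clusters into connected
components and merges fragments smaller than `S²/4` into their dominant
neighbor. No SLIC implementation exists in the R dependency stack used
here, so the clustering is implemented in the package; `stats::kmeans`
does the heavy lifting.

Superpixels with mean gray level above 240 are excluded as glass before
ranking — ranking "darkest first" presupposes tissue, and glass is
brighter than any stained tissue. There is deliberately **no** exclusion
on the dark side; that is what makes the pen-mark failure reproducible.
Candidates are superpixels whose mean is at or below the inclusive 10%
quantile of superpixel means, sorted ascending, ties broken by larger
area then lower label id. Pen-mark mitigation is a user-supplied
exclusion mask (any superpixel with more than half its area masked is
dropped); automatic ink detection is intentionally out of scope — the
workflow documents that human intervention is needed for such slides.

Crops are centered on the top candidate's centroid mapped through the
thumbnail scale factor and shifted (never padded) to fit the slide.

# Stain separation and normalization

The optical density image `X` (3 × n) is factorized as `X ≈ W L` with
`W` (3 × r) the color-appearance matrix and `L` (r × n) the nonnegative
density maps, by minimizing

```
0.5 * ||X - W L||_F^2 + lambda * sum_j ||W_j||_2 * ||L_j||_1
```

This is the scale-invariant form of the sparse separation objective: at
unit-norm columns of `W` (which the returned model always has) it equals
the familiar `0.5||X−WL||² + λ Σ ||L_j||_1`. Working with the
scale-invariant penalty matters numerically: with an unpenalized `W`,
alternating optimization inflates `||W||` to dodge the L1 penalty and
drifts to degenerate wide-cone solutions. Both block updates are exact
minimizers — per-row nonnegative lasso for `L`, a nonnegative
group-soft-threshold for each column of `W` — so the objective is
provably non-increasing at every iteration, and the final column
normalization (with the inverse scaling folded into `L`) changes
neither the product `W L` nor the objective value.

Details and defaults:

* `lambda = 0.1`, `r = 2`, convergence when the relative objective change
  drops below `1e-4`, at most 200 alternations.
* Fitting uses at most 20 000 tissue pixels (OD norm above 0.15),
  subsampled with the configured seed. Tissue pixels are
  lexicographically sorted before fitting, which makes the fit invariant
  to pixel permutation — and therefore exactly equivariant to image
  rotation, a property the segmentation backend inherits and the test
  suite asserts bit-exactly.
* Initialization is deterministic: OD directions are projected onto
  their top-2 eigenplane and the 1% / 99% angular extremes seed the two
  stain vectors (an angular grid for `r > 2`).
* Stain identity: the column with the larger red/green absorbance ratio
  is labeled hematoxylin. (Hematoxylin absorbs strongly in red and green;
  eosin almost exclusively in green — under the Ruifrok reference pair
  this rule orders the stains correctly.)
* Pixels at intensity 0 are clipped to 1 before the log so OD stays
  finite.

**Normalization** follows the pseudo-maximum recipe: each source density
row is multiplied by `RM(L_t)_j / RM(L_s)_j`, where `RM` is the 99%
quantile of the row over tissue pixels, then recombined with the
*target's* `W` and exponentiated. The stacked fraction in the published
formula is typographically ambiguous; multiply-by-target /
divide-by-source is the only orientation under which the normalized
densities inherit the target's scale, and the row-scaling test verifies
exactly that. When the transform is *applied*, densities are re-solved
by nonnegative least squares (`lambda = 0`) with `W` fixed: the L1
shrinkage that is useful while learning `W` would otherwise bias every
reconstructed pixel brighter by roughly `λ (WᵀW)⁻¹` density units,
violating the self-normalization identity (a source normalized to itself
must return unchanged within quantization error).

# Nuclei segmentation

**Classical backend (default for pipelines and tests).** Stain-separate,
take the hematoxylin density map, threshold by Otsu (256 levels), fill
holes, drop objects under 10 px. The path is fully deterministic and
rotation-equivariant. Touching nuclei are split by distance-transform
watershed only when *counting* objects; the binary mask itself is left
untouched.

**Network backend.** A U-Net-style encoder–decoder (configurable depth
and width; 3 × 3 convolutions, ReLU, 2 × 2 max-pool, nearest-neighbor
upsampling with skip concatenation, 1 × 1 softmax head) trained with
softmax cross-entropy, Adam, and the polynomial schedule
`lr_i = lr0 · (1 − i/N)^0.9` evaluated once per epoch. Protocol defaults
follow the established nuclei-segmentation recipe: `lr0 = 0.001`,
`N = 80` epochs, minibatch 2. The engine is plain R linear algebra
(im2col convolutions); all gradients are exact and finite-difference
checked in the tests. Cross-entropy is averaged per pixel and batch (the
summation convention is not fixed in the source material; the per-pixel
mean is the standard choice and is noted here as a convention).

The desk-scale training configuration used in the tests — 8 images of
64 × 64, depth 2, base width 12, 15 epochs — compresses the 80-epoch
protocol roughly twentyfold, so it uses a proportionally larger initial
rate (`lr0 = 0.03`); with 60 optimizer steps in total, the protocol rate
of 0.001 cannot move the weights far enough from initialization,
regardless of the task. The classification head is initialized at a
tenth of the He scale so training starts in the non-saturated regime of
the softmax. At such short schedules an occasional unlucky
initialization stalls at the class-prior solution (visible as a final
training loss near the prior entropy); `train_unet(..., restarts = k)`
trains k independently seeded replicates and keeps the one with the
lowest final *training* loss — a standard restart strategy that never
consults held-out data. The desk-scale runs use `restarts = 3`. MoNuSeg-style external training data is supported as an
optional input path but never required: tests train on synthetic pairs.

# Cellularity

`cellularity = foreground / total` after optional dilation with a disk
of diameter `d` (offsets with `i² + j² ≤ r²`, `r = (d−1)/2`) or a
square. Even diameters are reduced to `d − 1` (a centered disk needs an
odd support), with a message. Dilation sizes around 11–12 are the
literature convention for absorbing peri-nuclear cytoplasm; 0 (no
dilation) is the package default since the grading improvement from
dilation is marginal. Dilation goes through `EBImage::dilate`; the test
suite pins it to an exhaustive neighborhood-max oracle exactly, and
asserts monotone non-decrease in the element size.

Per-case cellularity is the mean over that case's ROIs (one ROI per case
in the default pipeline, making the two identical). All segmented nuclei
count toward cellularity: the upstream segmentation does not
discriminate cancerous from normal nuclei, so no such distinction is
invented here.

# Cascaded classification

Patches are tiled by a minimal evenly spaced covering grid:
`n = ceiling((dim − patch)/patch) + 1` windows per axis, offsets spread
from 0 to `dim − patch`. A 1000 × 1000 ROI with 512-px patches gives the
2 × 2 grid at stride 488; exact multiples tile without overlap. (A
discard-partial-tiles rule would yield a single patch for 1000 × 1000
and waste half the ROI.)

Augmentation (training only, fresh draws each epoch): rotation from
{0°, 90°, 180°, 270°}, flip from {none, horizontal, vertical}, isotropic
scale uniform in [0.95, 1.1] with center crop or edge-replicating pad
back to size.

**Stage 1** is a plain CNN: `conv–ReLU–maxpool` blocks (4 at production
defaults), global average pooling, then a dense head. **Stage 2** is the
deeper residual model: a stem convolution and residual blocks (6 at
production defaults, two convolutions each, identity shortcuts, pooling
while the spatial side is at least 8). The exact layer table of the
original networks lives in supplementary material not available here, so
depth and width are configurable with these defaults, and the invariant
`stage2_blocks ≥ stage1_blocks` (stage 2 is the deeper model) is kept.

**Fusion.** The 4-bit molecular vector (MT/CD/ML = 1) and the
cellularity scalar are concatenated to the pooled convolutional features
before the first dense layer. Side features are z-scored on the training
cases and the scaling is stored in the model; without this, the
cellularity scalar (dynamic range ≈ 0.1) is numerically invisible next
to the convolutional activations and the fusion benefit disappears at
desk-scale step counts.

**Decision rule.** Case-level mean of patch probabilities, threshold
0.5, ties resolved toward the higher grade (clinically conservative). An
HGG verdict short-circuits stage 2. Accuracy is reported case-level
(patch-level aggregation is an implementation detail of training, not of
evaluation).

**Cross-validation.** Stratified 5-fold at the case level: within each
grade, cases are shuffled and dealt round-robin, so each fold tests ~20%
of every grade (the 8:2 split) and no patch of a test case is ever seen
in training. Reports carry per-fold accuracies, their mean and sample
standard deviation ("mean% ± std%"), and the pooled confusion matrix.

**Molecular classification** (the reverse task — predicting IDH, 1p/19q
or ATRX from image-derived summaries, cellularity, histology and grade)
uses a single-hidden-layer network (`nnet`, 8 hidden units, weight decay
0.1, features standardized) under repeated stratified 5-fold CV (10
repeats by default; the repetition count is not fixed in the source
material). The relatively strong decay matters: with ~45–60 cases and
one-hot expansions, a lightly regularized network overfits the added
factors and the expected monotone benefit of adding histology and grade
is lost in variance.

# Pipeline orchestration

`run_pipeline()` executes synth → roi → normalize → segment →
cellularity → classify from a YAML configuration validated exhaustively
(all violations reported at once; unknown keys are errors). Every stage
records, per case, an md5 content hash of its inputs plus its
configuration; a rerun skips work whose key matches and whose outputs
exist. Keys hash *inputs*, not outputs — so corrupting an intermediate
file re-executes exactly the downstream cases that consumed it, while
the stage that produced it (whose inputs are unchanged) is not re-run.
A single global seed derives all per-stage seeds, and with the classical
segmentation backend the whole run is byte-deterministic: identical
configuration and seed reproduce the predictions CSV exactly.

# Problem sizes and numerical choices

The package's own test and acceptance runs use: 96 × 96 synthetic images
for stain work; 360 × 480 mock slides with 160-px thumbnails and ~120
superpixels; 128 × 128 images with 30 disjoint nuclei for segmentation
scoring; a 150-case cohort (50 per grade, 64 × 64 ROIs, 32-px patches,
reduced networks, 4 epochs at `lr0 = 0.01`) for the cascade; and 15-case
cohorts for pipeline integration. These sizes were chosen once as the
desk-scale study conditions; the same code paths accept full-scale
inputs (1000 × 1000 ROIs, 512-px patches, the 80-epoch protocol) by
configuration.

Other numerical choices: OD uses `-log(max(I,1)/I0)`; quantiles are R's
type-7 (linear interpolation) everywhere, including the pseudo-maximum;
Otsu runs on 256 bins; k-means uses Lloyd iterations capped at 10 with
grid seeding; Adam uses β₁ = 0.9, β₂ = 0.999, ε = 1e-8; max-pool ties
break toward the earliest window position (deterministic).

# Known limitations

* The synthetic stain model has no spatial texture within nuclei, so
  segmentation on synthetic data is easier than on real H&E; the Dice
  figures quoted by the tests bound algorithmic correctness, not
  clinical accuracy.
* Classification accuracies on the synthetic cohort measure *parameter
  recovery* of a generative process whose grade signal (nuclei density,
  molecular priors) is known to be present; they are not comparable to
  accuracies on patient cohorts.
* The pure-R network engine is CPU-bound and sized for small images;
  training 512-px patches at production depth is possible but slow.
* Pen-mark handling is deliberately manual (exclusion masks); no
  automatic artifact detection is attempted.
* Two stains only by default; `r > 2` is supported by the optimizer but
  the initialization is tuned for H&E.
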