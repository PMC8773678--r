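---
title: "Normative t-score mapping and patch-wise CNN detection of cerebral infarcts on CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative t-score mapping and patch-wise CNN detection of cerebral infarcts on CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infarctCT)
```

## The problem

Acute cerebral infarcts appear on non-contrast head CT as subtle
hypodensities: a drop of perhaps ten Hounsfield units (HU) against normal
parenchyma, in a modality where cerebrospinal fluid (CSF, about 0 HU) and
partial-volume effects produce similarly dark voxels. `infarctCT`
implements an automated patch-wise detection pipeline for volumes that
already live on a common template grid (the canonical grid is
181 x 217 x 181 voxels at 1 mm): every voxel of a patient scan is scored
against a cohort of lesion-free control scans, and a small convolutional
network classifies 16 x 16 tiles of the resulting statistic map as
infarcted or not. Spatial normalization itself (an SPM-style registration
step) is out of scope here; the package assumes its inputs are already
template-aligned, and its phantom generator emits volumes directly on that
grid.

## Preprocessing

**Intensity transformation.** Raw HU are mapped through an invertible
piecewise-linear function that stretches the parenchymal window:

| input HU          | map              | image         |
|-------------------|------------------|---------------|
| [-1000, -100]     | HU + 1000        | [0, 900]      |
| (-100, 100]       | 11 HU + 2000     | (900, 3100]   |
| (100, 1000]       | HU + 3000        | (3100, 4000]  |

The middle coefficients are the unique line through the printed range
endpoints (-99 maps to 911 and 100 to 3100), consistent with the
description of the parenchymal window being enlarged eleven-fold. The
three pieces join continuously, so the map is strictly increasing and
exactly invertible; `inverse_transform_intensity()` undoes it bitwise on
integer HU. Inputs outside [-1000, 1000] are clamped first — real CT
headers often pad with -1024 — which preserves monotonicity without
rejecting valid scans.

**Skull and CSF elimination.** The mean and standard deviation of all
strictly positive transformed voxels are computed (template-space
background transforms to exactly 0 and is excluded; the SD uses the
sample n-1 denominator), and voxels below mean - 2 SD (fluid) or above
mean + 2 SD (bone) are removed. Comparisons are strict, so values exactly
at a threshold stay in the parenchyma. No morphological cleanup is
applied. A caveat worth knowing: the rule's behaviour depends on the
composition of the positive-voxel pool. On our phantoms the bright skull
shell inflates the pooled SD enough that the lower threshold falls below
the CSF level, so thresholding removes the skull but retains ventricular
CSF; detection is unaffected because the retained CSF is identical across
subjects and therefore scores near zero, but the `ventricle_mask` can be
empty on phantom data.

**Smoothing.** A separable stationary Gaussian with 5-mm full width at
half maximum (FWHM = 2 * sqrt(2 ln 2) * sigma, so sigma is about 2.12 mm)
is applied per axis in voxel units. Because the skull and background have
just been zeroed, plain convolution would mix zeros into the parenchyma
rim and create artificial rim hypodensity — exactly the pattern the
detector is trained to flag. Smoothing is therefore normalized over the
parenchyma support by default (the ratio of the smoothed masked image to
the smoothed mask); `normalize = FALSE` restores plain convolution for
compatibility with SPM-style pipelines that smooth before masking.

## The normative model

From n preprocessed controls, `build_normative_maps()` stores the
voxel-wise mean and sample standard deviation. A patient voxel value $p$
is then scored with the Crawford–Howell single-case statistic

$$ t = \frac{p - \bar{X}_C}{\sqrt{(n+1)/n}\; s_C} $$

where the correction factor $\sqrt{(n+1)/n}$ accounts for the finite
control sample (for the reference cohort size n = 38 a unit deviation at
unit SD gives t = 0.9871 rather than 1). Voxels where the control SD is
below `eps = 1e-6` are excluded from the map's validity mask — phantom
cohorts can produce exactly zero variance, which would otherwise yield
infinite scores — and t is set to 0 off the mask. Hypodense lesions
produce negative t. The signed statistic is used as-is as classifier
input; mapping to absolute values would discard the sign that separates
hypodense infarcts from hyperdense artifacts.

## Patches, labels, augmentation

Each axial slice of the t-map is tiled into non-overlapping 16 x 16
patches anchored at the slice origin; only complete tiles whose every
pixel lies inside the map's mask are adopted. (For a full 181 x 217
slice this yields 143 complete tiles; the area quotient
$\lfloor 181\cdot217/256\rfloor = 153$ is an estimate only, since
complete disjoint tiles cannot reach it.) A patch is labeled infarcted
when it overlaps at least `min_lesion_pixels = 1` ground-truth lesion
pixels — the most literal reading of "contains some infarcted pixels".
One pixel of overlap makes labels intentionally noisy at lesion borders;
the threshold is configurable.

Augmentation shifts each adopted patch by 4 pixels (a quarter patch,
preserving substantial overlap with the original; the magnitude is a
design choice, not a reported value) along the eight compass directions.
A shifted candidate is rejected if any pixel leaves the mask or if its
label would differ from the original's. Class balancing keeps all
minority patches and subsamples the majority to at most 1.1 times the
minority count (the reference cohort's 2826 kept negatives against 2656
positives correspond to ratio 1.064); the train/validation split takes a
seeded random 80% (rounded half-up), and resampling the split with new
seeds supports repeated cross-validation. Both operations canonicalize
patch order before sampling, so results do not depend on collection
order.

## The classifier

The network is deliberately small: three blocks of (3 x 3 convolution,
batch normalization, ReLU, 2 x 2 max pooling) with 8, 16 and 32 filters,
a fully connected layer to 2 classes, dropout at rate 0.5, softmax, and a
cross-entropy classification output — 17 layers counting the input.
Kernel size, filter counts, padding and dropout placement are not
prescribed by the reference description beyond the layer enumeration;
the defaults here (stride 1, symmetric padding, dropout after the fully
connected layer, following the enumerated layer order) are configurable
in `cnn_config()`. Three pooling stages reduce 16 x 16 to 2 x 2, giving
128 features to the head.

Training is plain SGD with momentum 0.9, mini-batches of 500 (partial
final batches are used), L2 weight decay 0.005 on convolution and FC
weights, and a learning rate decaying geometrically per epoch from 1e-5
at the first epoch to 1e-7 at the last planned epoch; the planned run
length is `min(max_epochs, ceiling(max_iterations / steps_per_epoch))`
and whichever cap binds first stops training. Dropout and batch-norm
batch statistics are active only in training, so inference is
deterministic. All randomness (initialization, shuffling, dropout,
sampling) derives from explicit seeds; a fixed seed reproduces training
bitwise on a single worker.

These learning rates are very conservative. On the phantom benchmark
below the loss is still falling when a 2,000-iteration budget is
exhausted; the configuration is kept as specified rather than retuned,
and the consequences are discussed under Limitations.

## The phantom generator

No clinical data accompany the reference pipeline, so the package ships a
seeded phantom module that emulates the study's cohort structure (38
controls, 21 patients by default) on the template grid:

* an ellipsoidal brain with a white-matter core (25 HU), gray-matter
  shell (35 HU), two CSF-filled ventricles (0 HU), and a thin skull shell
  (1000 HU) in an air background; the tissue means are the standard
  brain-window values;
* per-subject tissue-mean jitter (SD 1 HU) and voxel-wise Gaussian noise
  (SD 3 HU) inside the head. The background is uniform air at exactly
  -1000 HU: after spatial normalization real template-space volumes have
  a constant background, and leaving noise there would place half the
  background voxels just above the transform's zero point and corrupt
  the positive-voxel statistics of the elimination step;
* patients additionally carry two hypodense lesions by default, each a union of
  overlapping spheres planted entirely inside the parenchyma, with a
  primary radius of 8-14 mm and an HU decrement drawn from 8-20 HU. The
  decrement range is a modeling choice — no quantitative HU drop for
  acute infarcts is reported in the reference — spanning subtle early to
  established hypodensity. Ground-truth masks mark exactly the lesioned
  voxels, standing in for MRI-derived delineations.

The default grid is 91 x 109 x 91 at 2 mm (half resolution) so that a
full cohort builds in minutes; the full 1-mm grid is supported. A sulcus
artifact generator (`add_sulcus_artifact()`) carves a CSF-filled groove
into the cortical surface to reproduce qualitatively the ageing-related
false-positive mechanism: the groove scores strongly negative t against
controls that lack it.

What the phantoms do *not* emulate: registration error (all subjects
share one geometry), CT physics (beam hardening, streaks, noise
correlation), anatomical variability, and the MRI-to-CT delay that blurs
clinical ground truth. Phantom results therefore bound the pipeline's
mechanics, not its clinical accuracy.

## Problem sizes used in the tests

The packaged test-suite and acceptance runs use the half-resolution grid
with 38 controls and 6 patients, about 1,000 lesion patches after
augmentation against an equal number of control patches, and a training
budget of 2,000 iterations; unit tests use smaller grids (48 x 56 x 48 at
4 mm) and cohorts chosen so each file runs in seconds.

## Numerical choices and degenerate inputs

* Threshold ties in the elimination step stay in parenchyma (strict
  inequalities); an all-equal volume removes nothing; a volume with no
  positive voxels is an error.
* Gaussian kernels are truncated at 4 sigma and renormalized, so an
  interior impulse conserves mass to machine precision; FWHM 0 is the
  identity.
* Max-pool ties route the gradient to the first maximum in column order,
  keeping training deterministic.
* Patch coordinates are 0-based half-open throughout; "slice" always
  means the axial (third) index.
* Lesion placement uses rejection sampling (200 attempts) and errors if
  the requested radius cannot fit inside the parenchyma.
* `balance_classes()` requires both classes; `split_dataset()` rejects
  empty datasets and fractions outside (0, 1).

## Limitations

* The classifier's hyperparameters are kept at their reference values.
  With the geometric decay from 1e-5 to 1e-7 the optimizer moves slowly;
  short training budgets (a few thousand iterations) leave the model
  short of its asymptote on the phantom benchmark, which shows up as
  depressed validation accuracy and an elevated control false-positive
  rate relative to a longer run. The package reports what the specified
  configuration achieves rather than what a retuned one could.
* Patch labels inherit the `min_lesion_pixels = 1` rule, so tiles
  brushing a lesion corner are counted as infarcted even though their
  content is mostly normal; patch-level metrics should be read with that
  label noise in mind.
* Statistical skull/CSF elimination is exactly the two-sided 2-SD rule;
  on data where bright voxels dominate the pooled variance it degrades
  gracefully (skull removed, CSF retained) as described above.
* Atlas lookup is a pure coordinate read-off; it is only as good as the
  alignment of the atlas to the template grid.
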