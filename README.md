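# infarctCT

Automated detection of cerebral infarcts on non-contrast head CT.

Acute ischemic infarcts are subtly hypodense on CT — often a drop of only
8–20 Hounsfield units (HU) against normal parenchyma, in a modality where
cerebrospinal fluid is just as dark. `infarctCT` implements a complete
patch-wise detection pipeline for template-aligned head CT volumes, aimed
at researchers studying statistical normative mapping and small-network
classifiers for stroke imaging:

1. **Contrast enhancement** — an invertible piecewise HU transformation
   that stretches the parenchymal window eleven-fold
   (`HU + 1000` on [−1000, −100], `11·HU + 2000` on (−100, 100],
   `HU + 3000` on (100, 1000]);
2. **Skull/CSF elimination** — two-sided thresholding at mean ± 2 SD of
   the positive voxels;
3. **Smoothing** — separable Gaussian, 5-mm FWHM, normalized over the
   parenchyma support;
4. **Normative t-score mapping** — every voxel of a patient scan is
   scored against a lesion-free control cohort with the Crawford–Howell
   single-case statistic

   t = (p − X̄_C) / (√((n+1)/n) · s_C),

   where X̄_C and s_C are the voxel-wise control mean and sample SD and
   n the control count;
5. **Patch classification** — axial slices of the t-map are tiled into
   16 × 16 patches; a 17-layer CNN (3 × [conv–batchnorm–ReLU–maxpool],
   FC, dropout, softmax, classification) labels each tile infarcted or
   non-infarcted, trained with SGDM, shift-based augmentation and class
   balancing;
6. **Localization** — detected tiles are mapped to atlas labels by pure
   coordinate lookup, and per-slice overlay reports are rendered.

Because no clinical data accompany the reference pipeline, the package
includes a fully seeded phantom module (`phantom_spec()`,
`generate_control()`, `generate_patient()`, `generate_cohort()`) that
builds control cohorts and lesioned patients with ground-truth masks on
the template grid, which the test suite uses for end-to-end evaluation.

## Worked example

A small phantom study: eight lesion-free controls form the normative
model, one patient carries two planted hypodense lesions (15–20 HU
decrement), and a classifier is trained on the patient's lesion tiles
against the controls' normal tiles.

```r
library(infarctCT)

spec <- phantom_spec(shape = c(64, 72, 64), voxel_size_mm = c(3, 3, 3),
                     seed = 7)
controls <- lapply(1:8, function(i) generate_control(spec, i))
fit <- fit_normative_cohort(controls)
fit$model
#> <normative_model> n = 8 controls, grid 64 x 72 x 64
#>   valid voxels: 91520; mean of mean_map on valid: 2350.3

patient <- generate_patient(spec,
                            lesion_spec(count = 2, radius_mm = c(16, 20),
                                        decrement_hu = c(15, 20),
                                        n_spheres = 1),
                            subject_seed = 30)
sum(patient$lesion_mask$data)   # ground-truth lesion voxels
#> [1] 1616

patches <- list()
for (i in 1:8) {
  tm <- compute_tscore_map(fit$preprocessed[[i]], fit$model,
                           fit$segmentations[[i]]$parenchyma_mask)
  patches <- c(patches, harvest_patches(tm, sprintf("control_%02d", i)))
}
pre <- preprocess_ct(patient$volume)
tm_p <- compute_tscore_map(pre$volume, fit$model,
                           pre$segmentation$parenchyma_mask)
patches <- c(patches, harvest_patches(tm_p, "patient_01",
                                      lesion_mask = patient$lesion_mask,
                                      augment = TRUE))
ds <- split_dataset(balance_classes(patches, seed = 5), 0.8, seed = 6)
ds
#> <patch_dataset> 321 patches (153 infarcted / 168 non-infarcted)
#>   split: 257 train / 64 validation

cnn <- train_cnn(build_cnn(seed = 7), ds,
                 train_config(lr_initial = 1e-5, lr_final = 1e-5,
                              max_iterations = 1200, batch_size = 100,
                              seed = 8))
cnn
#> <infarct_cnn> 17 layers, input 16x16, filters (8, 16, 32), trained
#>   trained 1200 iterations (400 epochs), final loss 0.4709, val accuracy 90.6%

det <- detect_infarcts(patient$volume, cnn, fit$model,
                       patient_id = "patient_01")
det
#> <infarct_detection> patient_01: 39/128 tiles classified infarcted
#>   slices involved: 13, 14, 15, 16, 17, 19, ...
head(det$detections, 3)
#>   slice row0 col0 probability
#> 1    13   32   32   0.5715941
#> 2    14   32   32   0.6400993
#> 3    15   16   32   0.6514731
```

The detection object lists each flagged tile by its 0-based axial slice
and top-left corner with the classifier's infarct probability;
`render_report()` writes per-slice overlays (red squares on the chosen
background), a CSV of detections, and a JSON summary, and
`map_patch_to_atlas()` / `localize_detections()` name the overlapped
atlas regions. A thin command-line front end over the same functions is
installed at `inst/cli/infarctct.R` (verbs `simulate-cohort`,
`build-normative`, `tscore`, `detect`).

See the methods vignette (`vignettes/methods.Rmd`) for the model's
assumptions, parameter choices, and known limitations.

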