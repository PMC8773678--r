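#' Fit a normative model from raw control volumes
#'
#' Applies the fixed control chain (intensity transformation, skull/CSF
#' elimination, smoothing) to every control and fits the voxel-wise
#' mean/SD model.
#'
#' @param controls list of [ct_volume()] objects in Hounsfield units on a
#'   common grid.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 5).
#' @return List with `model` (a `normative_model`), `preprocessed` (list of
#'   smoothed volumes) and `segmentations`.
#' @export
fit_normative_cohort <- function(controls, fwhm_mm = 5) {
  pre <- lapply(controls, preprocess_ct, fwhm_mm = fwhm_mm)
  vols <- lapply(pre, `[[`, "volume")
  segs <- lapply(pre, `[[`, "segmentation")
  list(model = build_normative_maps(vols), preprocessed = vols,
       segmentations = segs)
}

#' Harvest labeled patches from one t-score map
#'
#' Tiles the map, labels each adopted tile against the lesion mask (all
#' tiles are non-infarcted when no mask is given), and optionally augments
#' every tile by compass-direction shifting.
#'
#' @param tmap a `tscore_map`.
#' @param subject subject identifier stamped on each patch.
#' @param lesion_mask optional lesion [binary_mask()].
#' @param augment augment tiles by shifting (default `FALSE`).
#' @param shift_pixels augmentation shift magnitude.
#' @param min_lesion_pixels labeling threshold, see [label_patch()].
#' @param patch_size tile edge length.
#' @return List of labeled [ct_patch()] objects.
#' @export
harvest_patches <- function(tmap, subject, lesion_mask = NULL,
                            augment = FALSE, shift_pixels = 4,
                            min_lesion_pixels = 1, patch_size = 16) {
  tiles <- tile_patches(tmap, patch_size = patch_size)
  empty_mask <- binary_mask(array(FALSE, dim(tmap$t)), "lesion")
  lm <- lesion_mask %||% empty_mask
  out <- list()
  for (p in tiles) {
    p$subject <- as.character(subject)
    p <- label_patch(p, lm, min_lesion_pixels)
    out[[length(out) + 1L]] <- p
    if (augment) {
      aug <- augment_patch(p, tmap, lm, shift_pixels = shift_pixels,
                           min_lesion_pixels = min_lesion_pixels)
      for (a in aug) {
        a$subject <- as.character(subject)
        out[[length(out) + 1L]] <- a
      }
    }
  }
  out
}
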