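#' Construct a t-score patch
#'
#' A patch is the classifier's unit: a square matrix of t-scores cut from
#' one axial slice, addressed by its 0-based top-left corner (`row0`,
#' `col0`) and 0-based axial `slice` index.
#'
#' @param values square numeric matrix of t-scores.
#' @param slice,row0,col0 0-based patch coordinates.
#' @param label `"infarcted"`, `"non_infarcted"` or `"unlabeled"`.
#' @param provenance `"original"` or `"augmented:<direction>"`.
#' @param subject optional subject identifier (used for reproducible
#'   ordering of multi-subject collections).
#' @return An object of class `ct_patch`.
#' @export
ct_patch <- function(values, slice, row0, col0, label = "unlabeled",
                     provenance = "original", subject = NA_character_) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  label <- match.arg(label, c("infarcted", "non_infarcted", "unlabeled"))
  structure(
    list(values = values, slice = as.integer(slice),
         row0 = as.integer(row0), col0 = as.integer(col0),
         label = label, provenance = provenance,
         subject = as.character(subject)),
    class = "ct_patch"
  )
}

#' @export
print.ct_patch <- function(x, ...) {
  cat(sprintf("<ct_patch> %dx%d at slice %d (%d,%d) label=%s [%s]\n",
              nrow(x$values), ncol(x$values), x$slice, x$row0, x$col0,
              x$label, x$provenance))
  invisible(x)
}

patch_in_mask <- function(mask3, slice, row0, col0, size) {
  d <- dim(mask3)
  if (row0 < 0 || col0 < 0 || row0 + size > d[1] || col0 + size > d[2] ||
      slice < 0 || slice >= d[3]) return(FALSE)
  all(mask3[row0 + seq_len(size), col0 + seq_len(size), slice + 1L])
}

#' Tile a t-score map into non-overlapping complete patches
#'
#' Each axial slice is tiled on a grid anchored at its (0,0) corner; only
#' complete `patch_size` x `patch_size` tiles are produced, and a tile is
#' adopted only if every one of its pixels lies inside the t-map's mask
#' (inside the parenchyma, outside the ventricles).
#'
#' @param tmap a `tscore_map` from [compute_tscore_map()].
#' @param patch_size tile edge length in pixels (default 16).
#' @return List of [ct_patch()] objects (possibly empty).
#' @export
tile_patches <- function(tmap, patch_size = 16) {
  if (!inherits(tmap, "tscore_map"))
    stop("`tmap` must be a tscore_map", call. = FALSE)
  patch_size <- as.integer(patch_size)
  if (patch_size < 1) stop("`patch_size` must be >= 1", call. = FALSE)
  d <- dim(tmap$t)
  m <- tmap$mask$data
  row_starts <- seq.int(0L, by = patch_size,
                        length.out = d[1] %/% patch_size)
  col_starts <- seq.int(0L, by = patch_size,
                        length.out = d[2] %/% patch_size)
  out <- vector("list", 0L)
  idx <- seq_len(patch_size)
  for (k in seq_len(d[3])) {
    msl <- m[, , k]
    if (!any(msl)) next
    tsl <- tmap$t[, , k]
    for (r0 in row_starts) for (c0 in col_starts) {
      if (all(msl[r0 + idx, c0 + idx])) {
        out[[length(out) + 1L]] <- ct_patch(tsl[r0 + idx, c0 + idx],
                                            slice = k - 1L, row0 = r0,
                                            col0 = c0)
      }
    }
  }
  out
}

#' Label a patch against a lesion ground-truth mask
#'
#' A patch is `infarcted` when its footprint overlaps at least
#' `min_lesion_pixels` lesion pixels on its slice, `non_infarcted`
#' otherwise.
#'
#' @param patch a [ct_patch()].
#' @param lesion_mask a lesion [binary_mask()] on the same grid as the
#'   patch's source map.
#' @param min_lesion_pixels overlap threshold (default 1, "some infarcted
#'   pixels").
#' @return The patch with its `label` set.
#' @export
label_patch <- function(patch, lesion_mask, min_lesion_pixels = 1) {
  lm <- mask_data(lesion_mask)
  size <- nrow(patch$values)
  idx <- seq_len(size)
  overlap <- sum(lm[patch$row0 + idx, patch$col0 + idx, patch$slice + 1L])
  patch$label <- if (overlap >= min_lesion_pixels) "infarcted"
                 else "non_infarcted"
  patch
}

aug_directions <- function(shift) {
  s <- as.integer(shift)
  list(N = c(-s, 0L), NE = c(-s, s), E = c(0L, s), SE = c(s, s),
       S = c(s, 0L), SW = c(s, -s), W = c(0L, -s), NW = c(-s, -s))
}

#' Augment a labeled patch by compass-direction shifts
#'
#' Generates up to eight additional patches, one per compass direction,
#' each displaced by `shift_pixels` along the direction (diagonals shift
#' both axes). A candidate is rejected if the shift would change its label
#' (infarcted vs non-infarcted under [label_patch()]) or if any of its
#' pixels leaves the map's mask (out of parenchyma or into the ventricle).
#'
#' @param patch a labeled, adopted [ct_patch()].
#' @param tmap the `tscore_map` the patch came from.
#' @param lesion_mask lesion ground-truth [binary_mask()].
#' @param shift_pixels shift magnitude per direction (default 4).
#' @param min_lesion_pixels labeling threshold, see [label_patch()].
#' @return List of adopted augmented [ct_patch()] objects (0 to 8).
#' @export
augment_patch <- function(patch, tmap, lesion_mask, shift_pixels = 4,
                          min_lesion_pixels = 1) {
  if (patch$label == "unlabeled")
    stop("patch must be labeled before augmentation", call. = FALSE)
  size <- nrow(patch$values)
  idx <- seq_len(size)
  m <- tmap$mask$data
  out <- list()
  for (dir in names(aug_directions(shift_pixels))) {
    off <- aug_directions(shift_pixels)[[dir]]
    r0 <- patch$row0 + off[1]
    c0 <- patch$col0 + off[2]
    if (!patch_in_mask(m, patch$slice, r0, c0, size)) next
    cand <- ct_patch(tmap$t[r0 + idx, c0 + idx, patch$slice + 1L],
                     slice = patch$slice, row0 = r0, col0 = c0,
                     provenance = paste0("augmented:", dir),
                     subject = patch$subject)
    cand <- label_patch(cand, lesion_mask, min_lesion_pixels)
    if (cand$label != patch$label) next
    out[[length(out) + 1L]] <- cand
  }
  out
}

patch_labels <- function(patches) {
  vapply(patches, function(p) p$label, "")
}

# Canonical ordering key, so that seeded sampling is invariant to the
# order in which patches were collected.
patch_order <- function(patches) {
  order(vapply(patches, function(p) p$subject, ""),
        vapply(patches, function(p) p$slice, 0L),
        vapply(patches, function(p) p$row0, 0L),
        vapply(patches, function(p) p$col0, 0L),
        vapply(patches, function(p) p$provenance, ""))
}

#' Assemble a labeled patch collection
#'
#' @param patches list of labeled [ct_patch()] objects.
#' @param seed seed recorded with the dataset.
#' @return An object of class `patch_dataset`: list with `patches`
#'   (canonically ordered), `class_counts`, `split` (or `NULL`), `seed`.
#' @export
patch_dataset <- function(patches, seed = 0L) {
  patches <- patches[patch_order(patches)]
  labs <- patch_labels(patches)
  structure(
    list(patches = patches,
         class_counts = c(infarcted = sum(labs == "infarcted"),
                          non_infarcted = sum(labs == "non_infarcted")),
         split = NULL, seed = as.integer(seed)),
    class = "patch_dataset"
  )
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patches (%d infarcted / %d non-infarcted)\n",
              length(x$patches), x$class_counts[["infarcted"]],
              x$class_counts[["non_infarcted"]]))
  if (!is.null(x$split))
    cat(sprintf("  split: %d train / %d validation\n",
                sum(x$split == "train"), sum(x$split == "validation")))
  invisible(x)
}

#' Balance infarcted and non-infarcted classes
#'
#' Keeps every minority-class patch and randomly subsamples the majority
#' class down to at most `max_ratio` times the minority count (rounded to
#' nearest). Sampling is seeded and invariant to the input order.
#'
#' @param patches list of labeled [ct_patch()] objects containing both
#'   classes.
#' @param seed RNG seed for the subsample.
#' @param max_ratio maximum majority/minority ratio to retain (default 1.1).
#' @return A [patch_dataset()].
#' @export
balance_classes <- function(patches, seed, max_ratio = 1.1) {
  patches <- patches[patch_order(patches)]
  labs <- patch_labels(patches)
  n_inf <- sum(labs == "infarcted")
  n_non <- sum(labs == "non_infarcted")
  if (n_inf == 0 || n_non == 0)
    stop("both classes must be present to balance", call. = FALSE)
  minority <- if (n_inf <= n_non) "infarcted" else "non_infarcted"
  majority <- setdiff(c("infarcted", "non_infarcted"), minority)
  n_min <- min(n_inf, n_non)
  n_keep <- min(max(n_inf, n_non),
                as.integer(round_half_up(max_ratio * n_min)))
  maj_idx <- which(labs == majority)
  keep_maj <- with_seed(seed, sort(sample(maj_idx, n_keep)))
  kept <- sort(c(which(labs == minority), keep_maj))
  ds <- patch_dataset(patches[kept], seed = seed)
  ds
}

#' Split a patch dataset into training and validation sets
#'
#' The training set size is `train_fraction * n` rounded half-up to the
#' nearest integer; the assignment is a seeded uniform random partition.
#' Repeating the call with different seeds resamples the split (for
#' repeated cross-validation).
#'
#' @param ds a [patch_dataset()].
#' @param train_fraction fraction assigned to training, in (0, 1).
#' @param seed RNG seed for the partition.
#' @return The dataset with its `split` field set to a character vector of
#'   `"train"` / `"validation"` per patch.
#' @export
split_dataset <- function(ds, train_fraction = 0.8, seed = 0L) {
  if (!inherits(ds, "patch_dataset"))
    stop("`ds` must be a patch_dataset", call. = FALSE)
  n <- length(ds$patches)
  if (n == 0) stop("cannot split an empty dataset", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  n_train <- as.integer(round_half_up(train_fraction * n))
  train_idx <- with_seed(seed, sample(n, n_train))
  split <- rep("validation", n)
  split[train_idx] <- "train"
  ds$split <- split
  ds$seed <- as.integer(seed)
  ds
}

#' Serialize / load a patch dataset
#'
#' Writes a manifest CSV (patch id, subject, slice, row0, col0, label,
#' provenance, split) alongside an array container with the 16 x 16
#' matrices.
#'
#' @param ds a [patch_dataset()].
#' @param dir output directory.
#' @return `dir` (write) or a `patch_dataset` (read).
#' @export
write_patch_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$patches)
  manifest <- data.frame(
    id = seq_len(n),
    subject = vapply(ds$patches, function(p) p$subject, ""),
    slice = vapply(ds$patches, function(p) p$slice, 0L),
    row0 = vapply(ds$patches, function(p) p$row0, 0L),
    col0 = vapply(ds$patches, function(p) p$col0, 0L),
    label = patch_labels(ds$patches),
    provenance = vapply(ds$patches, function(p) p$provenance, ""),
    split = if (is.null(ds$split)) rep(NA_character_, n) else ds$split
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  size <- if (n > 0) nrow(ds$patches[[1]]$values) else 0L
  values <- array(0, c(size, size, n))
  for (i in seq_len(n)) values[, , i] <- ds$patches[[i]]$values
  saveRDS(list(values = values, seed = ds$seed),
          file.path(dir, "values.rds"))
  invisible(dir)
}

#' @rdname write_patch_dataset
#' @export
read_patch_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  blob <- readRDS(file.path(dir, "values.rds"))
  patches <- lapply(seq_len(nrow(manifest)), function(i) {
    ct_patch(blob$values[, , i], slice = manifest$slice[i],
             row0 = manifest$row0[i], col0 = manifest$col0[i],
             label = manifest$label[i], provenance = manifest$provenance[i],
             subject = manifest$subject[i])
  })
  ds <- patch_dataset(patches, seed = blob$seed)
  if (!all(is.na(manifest$split))) {
    # re-attach the split in the dataset's canonical order
    key <- function(m) paste(m$subject, m$slice, m$row0, m$col0,
                             m$provenance)
    stored <- manifest$split[order(manifest$subject, manifest$slice,
                                   manifest$row0, manifest$col0,
                                   manifest$provenance)]
    ds$split <- stored
  }
  ds
}

# Stack patch values into [size, size, n] plus labels for the classifier.
patch_array <- function(patches) {
  n <- length(patches)
  size <- nrow(patches[[1]]$values)
  x <- array(0, c(size, size, n))
  for (i in seq_len(n)) x[, , i] <- patches[[i]]$values
  list(x = x, labels = patch_labels(patches))
}
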