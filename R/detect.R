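#' End-to-end infarct detection on one patient volume
#'
#' Runs the patient preprocessing chain (intensity transformation, skull and
#' CSF elimination, Gaussian smoothing), computes the normative t-score map
#' against the control model, tiles every axial slice into complete
#' mask-interior patches, and classifies each adopted patch independently
#' with the trained network.
#'
#' @param patient a [ct_volume()] in Hounsfield units on the model's grid.
#' @param model a trained `infarct_cnn`.
#' @param normative a `normative_model` from [build_normative_maps()].
#' @param patient_id identifier carried into the report.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 5).
#' @param patch_size patch edge length (default: the model's input size).
#' @return An object of class `infarct_detection`: list with `patient_id`,
#'   `detections` (data frame of slice, row0, col0, probability for patches
#'   classified infarcted), `tiles` (all adopted tiles with predictions),
#'   `n_tiles`, `patch_size`, `shape`, and the intermediate `tscore_map`.
#' @export
detect_infarcts <- function(patient, model, normative,
                            patient_id = "patient", fwhm_mm = 5,
                            patch_size = NULL) {
  if (!isTRUE(model$trained)) stop("model has not been trained",
                                   call. = FALSE)
  if (!identical(dim(patient$data), dim(normative$mean_map)))
    stop("patient volume and normative model grids differ", call. = FALSE)
  patch_size <- patch_size %||% model$cfg$input_size
  pre <- preprocess_ct(patient, fwhm_mm = fwhm_mm)
  tmap <- compute_tscore_map(pre$volume, normative,
                             pre$segmentation$parenchyma_mask)
  tiles <- tile_patches(tmap, patch_size = patch_size)
  if (length(tiles) == 0) {
    det <- data.frame(slice = integer(), row0 = integer(),
                      col0 = integer(), probability = numeric())
    tile_df <- det
  } else {
    pred <- predict_patches(model, tiles)
    tile_df <- data.frame(
      slice = vapply(tiles, function(p) p$slice, 0L),
      row0 = vapply(tiles, function(p) p$row0, 0L),
      col0 = vapply(tiles, function(p) p$col0, 0L),
      label = pred$label,
      probability = pred$prob_infarcted
    )
    det <- tile_df[tile_df$label == "infarcted",
                   c("slice", "row0", "col0", "probability")]
    rownames(det) <- NULL
  }
  structure(
    list(patient_id = patient_id, detections = det, tiles = tile_df,
         n_tiles = length(tiles), patch_size = patch_size,
         shape = dim(patient$data), tscore_map = tmap),
    class = "infarct_detection"
  )
}

#' @export
print.infarct_detection <- function(x, ...) {
  cat(sprintf("<infarct_detection> %s: %d/%d tiles classified infarcted\n",
              x$patient_id, nrow(x$detections), x$n_tiles))
  if (nrow(x$detections) > 0) {
    sl <- sort(unique(x$detections$slice))
    cat(sprintf("  slices involved: %s\n", paste(sl, collapse = ", ")))
  }
  invisible(x)
}

#' Look up atlas regions under a patch footprint
#'
#' Because patient volumes, the template and the atlases share one
#' coordinate grid, localization needs no image processing: the labels
#' under the patch footprint are read off directly. All distinct nonzero
#' labels are returned with their pixel counts, largest first.
#'
#' @param slice,row0,col0 0-based patch coordinates.
#' @param atlas a list with `labels` (3-D integer label volume on the
#'   template grid) and optionally `names` (data frame with columns
#'   `label`, `name`).
#' @param patch_size patch edge length (default 16).
#' @return Data frame with columns `label`, `name`, `n_pixels`, sorted by
#'   `n_pixels` descending; zero rows if only background is covered.
#' @export
map_patch_to_atlas <- function(slice, row0, col0, atlas, patch_size = 16) {
  lab <- atlas$labels
  if (length(dim(lab)) != 3)
    stop("`atlas$labels` must be a 3-D label volume", call. = FALSE)
  d <- dim(lab)
  idx <- seq_len(patch_size)
  if (row0 < 0 || col0 < 0 || row0 + patch_size > d[1] ||
      col0 + patch_size > d[2] || slice < 0 || slice >= d[3])
    stop("patch footprint outside the atlas grid", call. = FALSE)
  vals <- lab[row0 + idx, col0 + idx, slice + 1L]
  vals <- vals[vals != 0]
  if (length(vals) == 0)
    return(data.frame(label = integer(), name = character(),
                      n_pixels = integer()))
  tab <- sort(table(vals), decreasing = TRUE)
  labels <- as.integer(names(tab))
  nm <- rep(NA_character_, length(labels))
  if (!is.null(atlas$names))
    nm <- atlas$names$name[match(labels, atlas$names$label)]
  data.frame(label = labels, name = nm, n_pixels = as.integer(tab),
             row.names = NULL)
}

#' Annotate detections with atlas regions
#'
#' @param result an `infarct_detection`.
#' @param atlas see [map_patch_to_atlas()].
#' @return The result with a `regions` list column added to `detections`.
#' @export
localize_detections <- function(result, atlas) {
  if (!identical(dim(atlas$labels), as.integer(result$shape)))
    stop("atlas and detection grids differ", call. = FALSE)
  result$detections$regions <- lapply(seq_len(nrow(result$detections)),
    function(i) {
      d <- result$detections[i, ]
      map_patch_to_atlas(d$slice, d$row0, d$col0, atlas,
                         result$patch_size)
    })
  result
}

slice_to_gray <- function(sl) {
  rng <- range(sl)
  if (diff(rng) == 0) return(array(0, dim(sl)))
  (sl - rng[1]) / diff(rng)
}

draw_rect_rgb <- function(img, r0, c0, size, lwd = 1) {
  d <- dim(img)
  rows <- (r0 + 1):min(r0 + size, d[1])
  cols <- (c0 + 1):min(c0 + size, d[2])
  edge_r <- unique(c(rows[seq_len(min(lwd, length(rows)))],
                     rev(rows)[seq_len(min(lwd, length(rows)))]))
  edge_c <- unique(c(cols[seq_len(min(lwd, length(cols)))],
                     rev(cols)[seq_len(min(lwd, length(cols)))]))
  img[edge_r, cols, 1] <- 1; img[edge_r, cols, 2:3] <- 0
  img[rows, edge_c, 1] <- 1; img[rows, edge_c, 2:3] <- 0
  img
}

#' Render a detection report
#'
#' Writes, under `dir`: one PNG overlay per axial slice containing at least
#' one detection (red squares over the grayscale background), a CSV table
#' of all detections, and a JSON summary. With zero detections the tables
#' are written empty and no overlays are produced.
#'
#' @param result an `infarct_detection`.
#' @param background a [ct_volume()] on the same grid used as the overlay
#'   background (for example the t-score map source or the transformed
#'   parenchyma image).
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of files written.
#' @export
render_report <- function(result, background, dir) {
  if (!identical(as.integer(dim(background$data)),
                 as.integer(result$shape)))
    stop("background and detection grids differ", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  det <- result$detections
  csv <- file.path(dir, paste0(result$patient_id, "_detections.csv"))
  utils::write.csv(det[, c("slice", "row0", "col0", "probability")], csv,
                   row.names = FALSE)
  files <- c(files, csv)
  summary <- list(
    patient_id = result$patient_id,
    n_tiles = result$n_tiles,
    n_detected = nrow(det),
    patch_size = result$patch_size,
    slices_with_detections = sort(unique(det$slice))
  )
  js <- file.path(dir, paste0(result$patient_id, "_summary.json"))
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA)
  files <- c(files, js)
  for (sl in sort(unique(det$slice))) {
    g <- slice_to_gray(background$data[, , sl + 1])
    img <- array(rep(g, 3), c(dim(g), 3))
    for (i in which(det$slice == sl))
      img <- draw_rect_rgb(img, det$row0[i], det$col0[i],
                           result$patch_size)
    f <- file.path(dir, sprintf("%s_slice%03d.png", result$patient_id, sl))
    png::writePNG(img, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' @describeIn detect_infarcts plot one axial slice with detection boxes
#'   (base graphics).
#' @param x an `infarct_detection`.
#' @param background background [ct_volume()].
#' @param slice 0-based axial slice to draw (default: first detected
#'   slice, or the middle slice if nothing was detected).
#' @param ... ignored.
#' @export
plot.infarct_detection <- function(x, background, slice = NULL, ...) {
  if (is.null(slice))
    slice <- if (nrow(x$detections) > 0) x$detections$slice[1]
             else x$shape[3] %/% 2
  sl <- background$data[, , slice + 1]
  graphics::image(seq_len(nrow(sl)), seq_len(ncol(sl)), sl,
                  col = grDevices::gray.colors(128), xlab = "sagittal",
                  ylab = "coronal",
                  main = sprintf("%s, slice %d", x$patient_id, slice))
  det <- x$detections[x$detections$slice == slice, ]
  if (nrow(det) > 0)
    graphics::rect(det$row0 + 0.5, det$col0 + 0.5,
                   det$row0 + x$patch_size + 0.5,
                   det$col0 + x$patch_size + 0.5, border = "red", lwd = 2)
  invisible(x)
}
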