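#' Voxel-wise average template of a control cohort
#'
#' Arithmetic mean across preprocessed control volumes, voxel by voxel.
#'
#' @param controls list of [ct_volume()] objects on a common grid, in
#'   transformed units.
#' @return A [ct_volume()] holding the voxel-wise mean.
#' @export
build_template <- function(controls) {
  if (length(controls) < 1) stop("need at least one control", call. = FALSE)
  ref <- controls[[1]]
  acc <- array(0, dim(ref$data))
  for (v in controls) {
    check_same_shape(ref, v, "control volumes")
    acc <- acc + v$data
  }
  out <- ref
  out$data <- acc / length(controls)
  out
}

#' Fit a voxel-wise normative model from a control cohort
#'
#' Computes, at every voxel, the mean and sample standard deviation (n-1
#' denominator) of the preprocessed control intensities. These maps, with
#' the control count n, are the reference distribution for the single-case
#' t statistic of [compute_tscore_map()]. The model also records, per voxel,
#' how many controls contributed a nonzero (parenchymal) value; voxels with
#' fewer than two contributors are marked invalid.
#'
#' @param controls list of at least two [ct_volume()] objects in transformed
#'   units on a common grid.
#' @return An object of class `normative_model`: list with `mean_map`,
#'   `sd_map` (3-D arrays), `n` (control count), `valid_mask`
#'   ([binary_mask()]), `voxel_size_mm`.
#' @export
build_normative_maps <- function(controls) {
  if (length(controls) < 2)
    stop("need at least two controls for a standard deviation map",
         call. = FALSE)
  ref <- controls[[1]]
  n <- length(controls)
  s1 <- array(0, dim(ref$data))
  s2 <- array(0, dim(ref$data))
  cnt <- array(0L, dim(ref$data))
  for (v in controls) {
    check_same_shape(ref, v, "control volumes")
    s1 <- s1 + v$data
    s2 <- s2 + v$data^2
    cnt <- cnt + (v$data > 0)
  }
  mean_map <- s1 / n
  # sample variance; guard tiny negatives from cancellation
  var_map <- pmax((s2 - n * mean_map^2) / (n - 1), 0)
  structure(
    list(mean_map = mean_map, sd_map = sqrt(var_map), n = n,
         valid_mask = binary_mask(cnt >= 2L, "parenchyma"),
         voxel_size_mm = ref$voxel_size_mm),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  d <- dim(x$mean_map)
  cat(sprintf("<normative_model> n = %d controls, grid %d x %d x %d\n",
              x$n, d[1], d[2], d[3]))
  cat(sprintf("  valid voxels: %d; mean of mean_map on valid: %.1f\n",
              sum(x$valid_mask$data),
              mean(x$mean_map[x$valid_mask$data])))
  invisible(x)
}

#' Single-case normative t-score map
#'
#' At each voxel inside the mask the patient value `p` is compared with the
#' control distribution by the Crawford-Howell single-case statistic
#' \deqn{t = (p - \bar{X}_C) / (\sqrt{(n+1)/n} \, s_C)}
#' where the `sqrt((n+1)/n)` factor accounts for the uncertainty of the
#' control mean and standard deviation at finite n. Voxels with control SD
#' below `eps` are excluded from the output mask (zero-variance voxels
#' would give infinite scores); off-mask voxels are set to 0.
#'
#' @param patient a preprocessed [ct_volume()] in transformed units on the
#'   model's grid.
#' @param model a `normative_model` from [build_normative_maps()].
#' @param parenchyma the patient's parenchyma [binary_mask()].
#' @param eps SD floor below which a voxel is excluded (default 1e-6).
#' @return An object of class `tscore_map`: list with `t` (3-D array),
#'   `mask` ([binary_mask()]), `n_used`, `voxel_size_mm`.
#' @export
compute_tscore_map <- function(patient, model, parenchyma, eps = 1e-6) {
  stopifnot_unit(patient, "transformed")
  if (!inherits(model, "normative_model"))
    stop("`model` must be a normative_model", call. = FALSE)
  if (model$n < 2) stop("model needs n >= 2 controls", call. = FALSE)
  if (!identical(dim(patient$data), dim(model$mean_map)))
    stop("patient volume and model grids differ", call. = FALSE)
  pm <- mask_data(parenchyma)
  if (!identical(dim(pm), dim(model$mean_map)))
    stop("parenchyma mask and model grids differ", call. = FALSE)
  mask <- pm & model$valid_mask$data & (model$sd_map >= eps)
  denom <- sqrt((model$n + 1) / model$n) * model$sd_map
  t <- array(0, dim(patient$data))
  t[mask] <- (patient$data[mask] - model$mean_map[mask]) / denom[mask]
  structure(
    list(t = t, mask = binary_mask(mask, "parenchyma"), n_used = model$n,
         voxel_size_mm = patient$voxel_size_mm),
    class = "tscore_map"
  )
}

#' @export
print.tscore_map <- function(x, ...) {
  d <- dim(x$t)
  on_mask <- x$t[x$mask$data]
  cat(sprintf("<tscore_map> grid %d x %d x %d, n = %d controls\n",
              d[1], d[2], d[3], x$n_used))
  if (length(on_mask))
    cat(sprintf("  %d masked voxels, t range [%.2f, %.2f]\n",
                length(on_mask), min(on_mask), max(on_mask)))
  invisible(x)
}

#' @describeIn build_normative_maps `predict` method: computes the t-score
#'   map of a preprocessed patient volume against the fitted model.
#' @param object a `normative_model`.
#' @param patient,parenchyma see [compute_tscore_map()].
#' @param ... passed on to [compute_tscore_map()].
#' @export
predict.normative_model <- function(object, patient, parenchyma, ...) {
  compute_tscore_map(patient, object, parenchyma, ...)
}

#' Serialize / load a normative model
#'
#' The model is stored as a pair of NIfTI volumes (mean and SD maps), a 0/1
#' NIfTI validity mask, and a JSON sidecar with the control count and
#' processing metadata.
#'
#' @param model a `normative_model`.
#' @param dir output directory (created if missing).
#' @return `dir` (write) or a `normative_model` (read).
#' @export
write_normative_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- model$voxel_size_mm
  write_volume(ct_volume(model$mean_map, vox, unit = "transformed"),
               file.path(dir, "mean.nii.gz"))
  write_volume(ct_volume(model$sd_map, vox, unit = "transformed"),
               file.path(dir, "sd.nii.gz"))
  write_volume(model$valid_mask, file.path(dir, "valid.nii.gz"))
  jsonlite::write_json(list(n = model$n, voxel_size_mm = vox),
                       file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_normative_model
#' @export
read_normative_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  mean_v <- read_volume(file.path(dir, "mean.nii.gz"), unit = "transformed")
  sd_v <- read_volume(file.path(dir, "sd.nii.gz"), unit = "transformed")
  valid <- read_mask(file.path(dir, "valid.nii.gz"), role = "parenchyma")
  structure(
    list(mean_map = mean_v$data, sd_map = sd_v$data, n = as.integer(meta$n),
         valid_mask = valid, voxel_size_mm = as.numeric(meta$voxel_size_mm)),
    class = "normative_model"
  )
}
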