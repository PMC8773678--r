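#' Piecewise contrast-enhancing intensity transformation
#'
#' Maps Hounsfield units onto a 0-4000 scale that stretches the parenchymal
#' window eleven-fold while leaving air and bone ranges merely shifted:
#' \itemize{
#'   \item HU in \[-1000, -100\]: `HU + 1000` (image 0-900),
#'   \item HU in (-100, 100\]: `11 * HU + 2000` (image (900, 3100\]),
#'   \item HU in (100, 1000\]: `HU + 3000` (image (3100, 4000\]).
#' }
#' The three pieces join continuously at -100 and 100, so the map is strictly
#' increasing and invertible. Inputs outside \[-1000, 1000\] are clamped
#' before mapping (CT headers commonly pad with -1024).
#'
#' @param vol a [ct_volume()] with unit `"HU"`.
#' @param clamp length-2 clamp range applied before mapping.
#' @return A [ct_volume()] with unit `"transformed"`, values in \[0, 4000\].
#' @seealso [inverse_transform_intensity()]
#' @examples
#' v <- ct_volume(array(c(-1000, 0, 25, 35, 1000), c(5, 1, 1)))
#' transform_intensity(v)$data[, 1, 1]
#' @export
transform_intensity <- function(vol, clamp = c(-1000, 1000)) {
  stopifnot_unit(vol, "HU")
  x <- pmin(pmax(vol$data, clamp[1]), clamp[2])
  y <- ifelse(x <= -100, x + 1000,
              ifelse(x <= 100, 11 * x + 2000, x + 3000))
  out <- vol
  out$data <- array(y, dim(vol$data))
  out$unit <- "transformed"
  out
}

#' Invert the piecewise intensity transformation
#'
#' Exact inverse of [transform_intensity()] on its image: values in
#' \[0, 900\] map back by `y - 1000`, values in (900, 3100\] by
#' `(y - 2000) / 11`, and values in (3100, 4000\] by `y - 3000`.
#'
#' @param vol a [ct_volume()] with unit `"transformed"`, values in
#'   \[0, 4000\].
#' @return A [ct_volume()] with unit `"HU"`.
#' @export
inverse_transform_intensity <- function(vol) {
  stopifnot_unit(vol, "transformed")
  y <- vol$data
  if (any(y < 0 | y > 4000))
    stop("transformed values must lie in [0, 4000]", call. = FALSE)
  x <- ifelse(y <= 900, y - 1000,
              ifelse(y <= 3100, (y - 2000) / 11, y - 3000))
  out <- vol
  out$data <- array(x, dim(y))
  out$unit <- "HU"
  out
}

#' Eliminate skull and CSF by statistical thresholding
#'
#' Computes the mean and standard deviation of all strictly positive voxels
#' (the template-space background transforms to 0 and is excluded), then
#' removes voxels below `mean - 2*sd` (ventricles/CSF) and above
#' `mean + 2*sd` (skull). Comparisons are strict, so ties at the thresholds
#' stay in the parenchyma. The returned volume equals the input on the
#' parenchyma and is 0 elsewhere.
#'
#' @param vol a [ct_volume()] with unit `"transformed"`.
#' @return A list with elements `volume` (masked [ct_volume()]) and
#'   `segmentation`, itself a list of `parenchyma_mask`, `ventricle_mask`,
#'   `skull_mask` ([binary_mask()] objects, pairwise disjoint), `mean`, `sd`.
#' @export
eliminate_skull_csf <- function(vol) {
  stopifnot_unit(vol, "transformed")
  x <- vol$data
  pos <- x > 0
  if (!any(pos))
    stop("volume has no positive voxels; nothing to segment", call. = FALSE)
  vals <- x[pos]
  m <- mean(vals)
  s <- stats::sd(vals) # n-1 denominator
  if (is.na(s)) s <- 0
  lo <- m - 2 * s
  hi <- m + 2 * s
  vent <- pos & (x < lo)
  skull <- pos & (x > hi)
  paren <- pos & !vent & !skull
  out <- vol
  out$data <- array(ifelse(paren, x, 0), dim(x))
  list(
    volume = out,
    segmentation = list(
      parenchyma_mask = binary_mask(paren, "parenchyma"),
      ventricle_mask = binary_mask(vent, "ventricle"),
      skull_mask = binary_mask(skull, "skull"),
      mean = m, sd = s
    )
  )
}

fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# 1-D convolution of a 3-D array along `axis` with zero padding,
# implemented as a weighted sum of shifted copies.
convolve_axis <- function(a, kernel, axis) {
  if (length(kernel) == 1L) return(a * kernel)
  d <- dim(a)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  for (i in seq_along(kernel)) {
    off <- i - r - 1L # contribution of a[pos + off] to out[pos]
    w <- kernel[i]
    if (w == 0) next
    dst <- seq.int(max(1L, 1L - off), min(n, n - off))
    src <- dst + off
    if (length(dst) == 0L) next
    if (axis == 1L) out[dst, , ] <- out[dst, , ] + w * a[src, , ]
    else if (axis == 2L) out[, dst, ] <- out[, dst, ] + w * a[, src, ]
    else out[, , dst] <- out[, , dst] + w * a[, , src]
  }
  out
}

gauss_smooth_array <- function(a, sigma_vox) {
  for (axis in 1:3) a <- convolve_axis(a, gauss_kernel_1d(sigma_vox[axis]),
                                       axis)
  a
}

#' Gaussian smoothing with FWHM in millimetres
#'
#' Separable stationary Gaussian filter. The per-axis sigma in voxels is
#' `fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm`. By default smoothing
#' is normalized over the nonzero support (normalized convolution): the
#' zeroed exterior left by [eliminate_skull_csf()] does not dilute interior
#' values, which would otherwise darken the parenchyma rim and mimic
#' infarcts. Set `normalize = FALSE` for plain convolution.
#'
#' @param vol a [ct_volume()].
#' @param fwhm_mm kernel full width at half maximum, in mm (>= 0; 0 is the
#'   identity).
#' @param normalize normalize over the nonzero support (default `TRUE`).
#' @param mask optional [binary_mask()] giving the support to normalize
#'   over; defaults to `vol$data != 0`.
#' @return A smoothed [ct_volume()] with the same tags.
#' @export
smooth_gaussian <- function(vol, fwhm_mm = 5, normalize = TRUE,
                            mask = NULL) {
  if (!is_ct_volume(vol)) stop("`vol` must be a ct_volume", call. = FALSE)
  if (!is.finite(fwhm_mm) || fwhm_mm < 0)
    stop("`fwhm_mm` must be a nonnegative number", call. = FALSE)
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / vol$voxel_size_mm
  out <- vol
  if (!normalize) {
    out$data <- gauss_smooth_array(vol$data, sigma_vox)
    return(out)
  }
  m <- if (is.null(mask)) vol$data != 0 else mask_data(mask)
  num <- gauss_smooth_array(vol$data * m, sigma_vox)
  den <- gauss_smooth_array(array(as.double(m), dim(vol$data)), sigma_vox)
  sm <- array(0, dim(vol$data))
  inside <- m & den > 0
  sm[inside] <- num[inside] / den[inside]
  out$data <- sm
  out
}

#' Preprocess one template-space CT volume
#'
#' The fixed per-subject chain: intensity transformation, statistical
#' skull/CSF elimination, then mask-normalized Gaussian smoothing. The same
#' chain serves controls (before cohort statistics) and patients (before
#' t-score mapping).
#'
#' @param vol a [ct_volume()] in Hounsfield units on the template grid.
#' @param fwhm_mm smoothing kernel FWHM in mm (default 5).
#' @return A list with `volume` (smoothed, parenchyma-only
#'   [ct_volume()]) and `segmentation` (see [eliminate_skull_csf()]).
#' @export
preprocess_ct <- function(vol, fwhm_mm = 5) {
  tr <- transform_intensity(vol)
  el <- eliminate_skull_csf(tr)
  sm <- smooth_gaussian(el$volume, fwhm_mm = fwhm_mm,
                        mask = el$segmentation$parenchyma_mask)
  list(volume = sm, segmentation = el$segmentation)
}
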