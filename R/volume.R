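#' @useDynLib infarctCT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a CT volume
#'
#' The pipeline's central container: a 3-D scalar grid with a voxel size, a
#' space tag and a unit tag. Axis order is (sagittal, coronal, axial), so an
#' axial slice is `vol$data[, , k]`; the template grid convention is
#' 181 x 217 x 181 voxels at 1 mm isotropic.
#'
#' @param data 3-D numeric array.
#' @param voxel_size_mm numeric length-3, all strictly positive (mm).
#' @param space `"native"` or `"template"`.
#' @param unit `"HU"`, `"transformed"` or `"tscore"`.
#' @return An object of class `ct_volume`.
#' @examples
#' v <- ct_volume(array(0, c(8, 8, 8)), c(1, 1, 1))
#' dim(v$data)
#' @export
ct_volume <- function(data, voxel_size_mm = c(1, 1, 1), space = "native",
                      unit = "HU") {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three positive values", call. = FALSE)
  space <- match.arg(space, c("native", "template"))
  unit <- match.arg(unit, c("HU", "transformed", "tscore"))
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm, space = space,
         unit = unit),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  cat(sprintf("  space: %s, unit: %s, range: [%.4g, %.4g]\n",
              x$space, x$unit, min(x$data), max(x$data)))
  invisible(x)
}

is_ct_volume <- function(x) inherits(x, "ct_volume")

stopifnot_unit <- function(vol, unit) {
  if (!is_ct_volume(vol))
    stop("expected a `ct_volume`", call. = FALSE)
  if (vol$unit != unit)
    stop(sprintf("expected a volume in %s units, got %s", unit, vol$unit),
         call. = FALSE)
  invisible(vol)
}

#' Construct a binary mask
#'
#' A boolean grid sharing the shape of its companion volume; `role` records
#' what the mask delineates.
#'
#' @param data 3-D logical (or 0/1 numeric) array.
#' @param role one of `"parenchyma"`, `"ventricle"`, `"skull"`, `"lesion"`,
#'   `"atlas"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, role = "parenchyma") {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  role <- match.arg(role, c("parenchyma", "ventricle", "skull", "lesion",
                            "atlas"))
  storage.mode(data) <- "logical"
  structure(list(data = data, role = role), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> role=%s, %d x %d x %d, %d voxels set\n",
              x$role, d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

mask_data <- function(m) {
  if (inherits(m, "binary_mask")) m$data
  else if (is.array(m) || is.logical(m)) {
    m <- m != 0
    m
  } else stop("not a mask", call. = FALSE)
}

check_same_shape <- function(a, b, what = "inputs") {
  da <- if (is_ct_volume(a)) dim(a$data) else dim(mask_data(a))
  db <- if (is_ct_volume(b)) dim(b$data) else dim(mask_data(b))
  if (!identical(da, db))
    stop(sprintf("%s must share a grid shape (%s vs %s)", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  invisible(TRUE)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All package randomness funnels through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible 31-bit child seed from a base seed and an index.
child_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Area-based estimate of complete patches per axial slice
#'
#' The number of `patch_size^2`-pixel tiles a slice can hold if the full slice
#' area were divisible into patches: `floor(nrow * ncol / patch_size^2)`. For
#' a 181 x 217 template slice with 16-pixel patches this gives 153, an
#' approximation; the exact count of complete disjoint tiles anchored at the
#' slice origin is `floor(181/16) * floor(217/16) = 143`.
#'
#' @param n_row,n_col slice dimensions in pixels.
#' @param patch_size patch edge length in pixels.
#' @return Integer patch-count estimate.
#' @export
slice_patch_estimate <- function(n_row = 181, n_col = 217, patch_size = 16) {
  as.integer(floor(n_row * n_col / patch_size^2))
}
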