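#' Read a volume from NIfTI-1 (or a DICOM series directory)
#'
#' NIfTI-1 is the pipeline's canonical interchange format. If `path` is a
#' directory it is treated as a single-series DICOM folder: slices are sorted
#' by position along the slice normal (instance number as fallback) and the
#' rescale slope/intercept is applied so the returned grid is in Hounsfield
#' units.
#'
#' @param path a `.nii`/`.nii.gz` file or a DICOM series directory.
#' @param unit unit tag to attach (`"HU"`, `"transformed"`, `"tscore"`).
#'   Defaults to `"HU"`; headers do not record the pipeline's unit.
#' @param space space tag to attach (`"native"` or `"template"`).
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, unit = "HU", space = "native") {
  if (dir.exists(path)) return(read_dicom_series(path, unit = unit,
                                                 space = space))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)
  data <- as.array(img)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L)
    data <- array(data, dim(data)[1:3])
  if (length(dim(data)) != 3L)
    stop("expected a 3-D volume in ", path, call. = FALSE)
  data <- array(as.vector(data), dim(data)) # drop RNifti attributes
  ct_volume(data, voxel_size_mm = vox[1:3], space = space, unit = unit)
}

#' Write a volume or mask to NIfTI-1
#'
#' Values are stored as float64 so that round trips are bitwise for integer
#' Hounsfield grids and exact for t-score maps. Masks are written as 0/1.
#'
#' @param vol a [ct_volume()] or [binary_mask()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "binary_mask")) {
    data <- array(as.double(vol$data), dim(vol$data))
    vox <- c(1, 1, 1)
  } else if (is_ct_volume(vol)) {
    data <- vol$data
    storage.mode(data) <- "double"
    vox <- vol$voxel_size_mm
  } else stop("`vol` must be a ct_volume or binary_mask", call. = FALSE)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- vox
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a mask from NIfTI-1
#'
#' @param path NIfTI file containing 0/1 values.
#' @param role mask role tag, see [binary_mask()].
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, role = "lesion") {
  v <- read_volume(path)
  binary_mask(v$data != 0, role = role)
}

# ---- minimal DICOM series reader (explicit VR little endian) ----
# Supports uncompressed single-frame CT slices with the tags the pipeline
# needs; anything else is rejected as a format error.

dcm_read_element <- function(con) {
  grp <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                 endian = "little")
  if (length(grp) == 0) return(NULL)
  ele <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                 endian = "little")
  vr <- rawToChar(readBin(con, "raw", 2))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    readBin(con, "raw", 2) # reserved
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    len <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                   endian = "little")
  }
  if (len < 0) stop("undefined-length DICOM element not supported",
                    call. = FALSE)
  value <- readBin(con, "raw", len)
  list(group = grp, element = ele, vr = vr, value = value)
}

dcm_parse_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 128)
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!identical(magic, "DICM"))
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  tags <- list()
  repeat {
    el <- dcm_read_element(con)
    if (is.null(el)) break
    key <- sprintf("%04x,%04x", el$group, el$element)
    tags[[key]] <- el
    if (el$group == 0x7fe0 && el$element == 0x0010) break
  }
  tags
}

dcm_string <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value))
}

dcm_numeric <- function(tags, key) {
  s <- dcm_string(tags, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16 <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", 1, size = 2, signed = FALSE,
          endian = "little")
}

#' Read a DICOM series directory as one CT volume
#'
#' Minimal reader for uncompressed explicit-VR little-endian CT series.
#' Slices are sorted by the projection of the image position onto the slice
#' normal; rescale slope and intercept convert stored values to Hounsfield
#' units. Mixed in-plane orientations within one series are a format error.
#'
#' @inheritParams read_volume
#' @param dir directory containing one `.dcm` file per slice.
#' @return A [ct_volume()] in Hounsfield units.
#' @export
read_dicom_series <- function(dir, unit = "HU", space = "native") {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0)
    files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no DICOM files in ", dir, call. = FALSE)
  slices <- lapply(files, function(f) {
    tags <- dcm_parse_file(f)
    rows <- dcm_uint16(tags, "0028,0010")
    cols <- dcm_uint16(tags, "0028,0011")
    bits <- dcm_uint16(tags, "0028,0100")
    signed <- identical(dcm_uint16(tags, "0028,0103"), 1L)
    if (is.null(rows) || is.null(cols) || is.null(bits))
      stop("missing image geometry tags in ", f, call. = FALSE)
    if (bits != 16L) stop("only 16-bit DICOM pixel data supported",
                          call. = FALSE)
    pix <- tags[["7fe0,0010"]]
    if (is.null(pix)) stop("missing pixel data in ", f, call. = FALSE)
    vals <- readBin(pix$value, "integer", rows * cols, size = 2,
                    signed = signed, endian = "little")
    slope <- dcm_numeric(tags, "0028,1053")
    inter <- dcm_numeric(tags, "0028,1052")
    if (is.null(slope)) slope <- 1
    if (is.null(inter)) inter <- 0
    list(
      # DICOM stores row-major; fill R matrix by row (rows x cols)
      data = matrix(vals * slope + inter, nrow = rows, ncol = cols,
                    byrow = TRUE),
      pos = dcm_numeric(tags, "0020,0032"),
      orient = dcm_numeric(tags, "0020,0037"),
      instance = dcm_numeric(tags, "0020,0013"),
      spacing = dcm_numeric(tags, "0028,0030"),
      thickness = dcm_numeric(tags, "0018,0050")
    )
  })
  orients <- unique(vapply(slices, function(s)
    paste(signif(s$orient, 6), collapse = ","), ""))
  if (length(orients) > 1)
    stop("inconsistent DICOM series: mixed image orientations",
         call. = FALSE)
  # sort by position along the slice normal, fall back to instance number
  ord <- NULL
  if (!is.null(slices[[1]]$pos) && !is.null(slices[[1]]$orient)) {
    o <- slices[[1]]$orient
    normal <- c(o[2] * o[6] - o[3] * o[5],
                o[3] * o[4] - o[1] * o[6],
                o[1] * o[5] - o[2] * o[4])
    proj <- vapply(slices, function(s) sum(s$pos * normal), 0)
    ord <- order(proj)
  } else if (!is.null(slices[[1]]$instance)) {
    ord <- order(vapply(slices, function(s) s$instance[1], 0))
  } else ord <- seq_along(slices)
  slices <- slices[ord]
  shapes <- unique(vapply(slices, function(s) paste(dim(s$data),
                                                    collapse = "x"), ""))
  if (length(shapes) > 1)
    stop("inconsistent DICOM series: mixed slice shapes", call. = FALSE)
  d <- dim(slices[[1]]$data)
  data <- array(0, c(d[1], d[2], length(slices)))
  for (k in seq_along(slices)) data[, , k] <- slices[[k]]$data
  spacing <- slices[[1]]$spacing %||% c(1, 1)
  dz <- slices[[1]]$thickness %||% 1
  if (length(slices) > 1 && !is.null(slices[[1]]$pos)) {
    gap <- abs(sum((slices[[2]]$pos - slices[[1]]$pos)^2))
    if (gap > 0) dz <- sqrt(gap)
  }
  ct_volume(data, voxel_size_mm = c(spacing[1], spacing[2], dz),
            space = space, unit = unit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
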