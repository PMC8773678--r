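# Fixtures and independent oracles shared across the test files.
# Everything is generated in code at test time; no binary files live in the
# repository.

# Construct a t-score map object directly from an array and mask, bypassing
# the normative pipeline, for tiling/augmentation tests.
make_tmap <- function(t, mask = NULL, n_used = 38) {
  if (is.null(mask)) mask <- array(TRUE, dim(t))
  structure(
    list(t = t, mask = binary_mask(mask, "parenchyma"),
         n_used = n_used, voxel_size_mm = c(1, 1, 1)),
    class = "tscore_map"
  )
}

# ---- synthetic DICOM series writer (explicit VR little endian) ----

dcm_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    v <- charToRaw(value)
    if (length(v) %% 2 == 1) v <- c(v, charToRaw(" "))
  } else if (vr == "US") {
    v <- writeBin(as.integer(value), raw(), size = 2, endian = "little")
  } else {
    v <- value # already raw
  }
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(element), raw(), size = 2,
                     endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    head <- c(head, raw(2),
              writeBin(length(v), raw(), size = 4, endian = "little"))
  } else {
    head <- c(head, writeBin(length(v), raw(), size = 2, endian = "little"))
  }
  c(head, v)
}

# Write one slice; `values` is a rows x cols integer matrix of stored
# (pre-rescale) values.
write_dicom_slice <- function(path, values, z_mm, instance,
                              slope = 1, intercept = -1024,
                              spacing = c(0.49, 0.49), thickness = 5,
                              orient = "1\\0\\0\\0\\1\\0") {
  pix <- writeBin(as.integer(t(values)), raw(), size = 2,
                  endian = "little")
  body <- c(
    dcm_element(0x0018, 0x0050, "DS", as.character(thickness)),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_element(0x0020, 0x0032, "DS", sprintf("0\\0\\%g", z_mm)),
    dcm_element(0x0020, 0x0037, "DS", orient),
    dcm_element(0x0028, 0x0010, "US", nrow(values)),
    dcm_element(0x0028, 0x0011, "US", ncol(values)),
    dcm_element(0x0028, 0x0030, "DS",
                paste(spacing, collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", 16),
    dcm_element(0x0028, 0x0103, "US", 0),
    dcm_element(0x0028, 0x1052, "DS", as.character(intercept)),
    dcm_element(0x0028, 0x1053, "DS", as.character(slope)),
    dcm_element(0x7fe0, 0x0010, "OW", pix)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# ---- brute-force augmentation oracle ----
# Independent re-statement of the adoption rules: a shifted candidate is
# adopted iff it stays in bounds, every pixel is inside the mask, and its
# lesion-overlap label equals the original patch's label.
oracle_augment <- function(mask3, lesion3, slice, row0, col0, size,
                           shift, min_lesion = 1) {
  offs <- list(N = c(-shift, 0), NE = c(-shift, shift), E = c(0, shift),
               SE = c(shift, shift), S = c(shift, 0), SW = c(shift, -shift),
               W = c(0, -shift), NW = c(-shift, -shift))
  lab_of <- function(r0, c0) {
    ov <- sum(lesion3[r0 + seq_len(size), c0 + seq_len(size), slice + 1])
    if (ov >= min_lesion) "infarcted" else "non_infarcted"
  }
  orig_lab <- lab_of(row0, col0)
  adopted <- character()
  d <- dim(mask3)
  for (nm in names(offs)) {
    r0 <- row0 + offs[[nm]][1]
    c0 <- col0 + offs[[nm]][2]
    if (r0 < 0 || c0 < 0 || r0 + size > d[1] || c0 + size > d[2]) next
    if (!all(mask3[r0 + seq_len(size), c0 + seq_len(size), slice + 1]))
      next
    if (lab_of(r0, c0) != orig_lab) next
    adopted <- c(adopted, nm)
  }
  adopted
}

# Small phantom spec used by fast end-to-end unit tests: coarse enough to
# preprocess in under a second, fine enough that a planted lesion still
# covers whole 16 x 16 tiles.
tiny_spec <- function(seed = 7) {
  phantom_spec(shape = c(64, 72, 64), voxel_size_mm = c(3, 3, 3),
               seed = seed)
}
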