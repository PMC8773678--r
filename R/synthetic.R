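#' Phantom cohort specification
#'
#' Describes the geometry and tissue statistics of the synthetic head
#' phantoms used in place of clinical data: an ellipsoidal brain with an
#' inner white-matter ellipsoid, a gray-matter shell, two ventricles filled
#' with CSF, and a thin skull shell, on the template grid. Tissue means are
#' the standard brain-window Hounsfield values (CSF 0, white matter 25,
#' gray matter 35; air -1000, bone 1000). Each subject draws a per-tissue
#' mean offset (scanner/biological variation) and voxel-wise Gaussian noise
#' inside the head; the background is uniform air, which the intensity
#' transformation maps to exactly 0.
#'
#' @param shape grid shape; default 91 x 109 x 91 (half-resolution template
#'   at 2 mm; the full 181 x 217 x 181 1-mm grid is supported).
#' @param voxel_size_mm voxel size matching `shape`.
#' @param tissue_hu named means for `background`, `csf`, `wm`, `gm`,
#'   `skull`.
#' @param noise_sd voxel noise SD in HU (default 3).
#' @param jitter_sd per-subject tissue-mean offset SD in HU (default 1).
#' @param seed cohort-level seed combined with each subject's seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(91, 109, 91),
                         voxel_size_mm = c(2, 2, 2),
                         tissue_hu = c(background = -1000, csf = 0,
                                       wm = 25, gm = 35, skull = 1000),
                         noise_sd = 3, jitter_sd = 1, seed = 0L) {
  stopifnot(length(shape) == 3, all(shape >= 16))
  hu <- tissue_hu
  if (!(hu[["background"]] < hu[["csf"]] && hu[["csf"]] < hu[["wm"]] &&
        hu[["wm"]] < hu[["gm"]] && hu[["gm"]] < hu[["skull"]]))
    stop("tissue means must be ordered background < CSF < WM < GM < skull",
         call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(shape = as.integer(shape), voxel_size_mm = as.numeric(voxel_size_mm),
         tissue_hu = hu, noise_sd = noise_sd, jitter_sd = jitter_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Tissue label volume: 0 background, 1 CSF (ventricles), 2 WM, 3 GM,
# 4 skull. Geometry is a pure function of the spec shape.
phantom_labels <- function(spec) {
  d <- spec$shape
  ctr <- (d + 1) / 2
  xs <- (seq_len(d[1]) - ctr[1])
  ys <- (seq_len(d[2]) - ctr[2])
  zs <- (seq_len(d[3]) - ctr[3])
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)
  semi_brain <- 0.42 * d
  r2 <- function(sx, sy, sz, cx = 0, cy = 0, cz = 0)
    ((X - cx) / sx)^2 + ((Y - cy) / sy)^2 + ((Z - cz) / sz)^2
  brain <- r2(semi_brain[1], semi_brain[2], semi_brain[3]) <= 1
  outer_skull <- r2(semi_brain[1] * 1.07, semi_brain[2] * 1.07,
                    semi_brain[3] * 1.07) <= 1
  wm <- r2(semi_brain[1] * 0.62, semi_brain[2] * 0.66,
           semi_brain[3] * 0.62) <= 1
  vent_semi <- c(0.07, 0.18, 0.10) * d
  voff <- 0.09 * d[1]
  vent <- (r2(vent_semi[1], vent_semi[2], vent_semi[3], cx = -voff) <= 1) |
          (r2(vent_semi[1], vent_semi[2], vent_semi[3], cx = voff) <= 1)
  if (!any(vent & brain) || any(vent & !brain))
    stop("degenerate phantom geometry: ventricles must lie inside the brain",
         call. = FALSE)
  lab <- array(0L, d)
  lab[outer_skull & !brain] <- 4L
  lab[brain] <- 3L           # gray-matter shell
  lab[brain & wm] <- 2L      # white matter core
  lab[vent] <- 1L            # ventricles override
  lab
}

phantom_parenchyma_mask <- function(spec) {
  lab <- phantom_labels(spec)
  binary_mask(lab == 2L | lab == 3L, "parenchyma")
}

phantom_hu_from_labels <- function(spec, lab) {
  hu <- spec$tissue_hu
  jit <- stats::rnorm(4, 0, spec$jitter_sd) # csf, wm, gm, skull
  means <- c(hu[["background"]], hu[["csf"]] + jit[1], hu[["wm"]] + jit[2],
             hu[["gm"]] + jit[3], hu[["skull"]] + jit[4])
  vol <- array(means[lab + 1L], dim(lab))
  head <- lab > 0L
  vol[head] <- vol[head] + stats::rnorm(sum(head), 0, spec$noise_sd)
  vol
}

#' Generate one lesion-free control phantom
#'
#' Deterministic for a fixed pair of cohort seed (`spec$seed`) and
#' `subject_seed`.
#'
#' @param spec a [phantom_spec()].
#' @param subject_seed per-subject seed.
#' @return A [ct_volume()] in Hounsfield units on the spec grid.
#' @export
generate_control <- function(spec, subject_seed = 1L) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec",
                                            call. = FALSE)
  lab <- phantom_labels(spec)
  vol <- with_seed(child_seed(spec$seed, subject_seed),
                   phantom_hu_from_labels(spec, lab))
  ct_volume(vol, voxel_size_mm = spec$voxel_size_mm, space = "template",
            unit = "HU")
}

#' Lesion specification for patient phantoms
#'
#' Each lesion is a union of overlapping spheres planted fully inside the
#' parenchyma (white + gray matter) with a sampled Hounsfield decrement;
#' infarcts are hypodense on CT, so the decrement is strictly positive.
#' The 8-20 HU default range is a modeling choice spanning subtle early to
#' clearly established hypodensities.
#'
#' @param count lesions per patient (default 2).
#' @param radius_mm range of the primary sphere radius (default 8-14 mm).
#' @param decrement_hu range of the HU decrement (default 8-20).
#' @param n_spheres spheres per lesion (default 3; satellites are smaller
#'   and overlap the primary sphere).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(count = 2, radius_mm = c(8, 14),
                        decrement_hu = c(8, 20), n_spheres = 3) {
  if (any(decrement_hu <= 0))
    stop("`decrement_hu` must be strictly positive (hypodense lesions)",
         call. = FALSE)
  structure(
    list(count = as.integer(count), radius_mm = as.numeric(radius_mm),
         decrement_hu = as.numeric(decrement_hu),
         n_spheres = as.integer(n_spheres)),
    class = "lesion_spec"
  )
}

sphere_mask <- function(shape, center, radius_vox) {
  d <- shape
  X <- array(rep(seq_len(d[1]) - center[1], times = d[2] * d[3]), d)
  Y <- array(rep(rep(seq_len(d[2]) - center[2], each = d[1]),
                 times = d[3]), d)
  Z <- array(rep(seq_len(d[3]) - center[3], each = d[1] * d[2]), d)
  X^2 + Y^2 + Z^2 <= radius_vox^2
}

#' Generate a patient phantom with planted hypodense lesions
#'
#' Samples lesion centers uniformly among parenchymal voxels whose primary
#' sphere fits entirely within the parenchyma (rejection sampling), carves
#' the lesion as a union of overlapping spheres, lowers the underlying
#' tissue HU by the sampled decrement, and returns the matching ground
#' truth mask. With `lesions$count == 0` the output is identical to
#' [generate_control()] for the same seeds.
#'
#' @param spec a [phantom_spec()].
#' @param lesions a [lesion_spec()].
#' @param subject_seed per-subject seed.
#' @return List with `volume` ([ct_volume()], HU), `lesion_mask`
#'   ([binary_mask()]), and `lesions` (data frame of sphere centers, radii
#'   in voxels, and decrements).
#' @export
generate_patient <- function(spec, lesions = lesion_spec(),
                             subject_seed = 1L) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec",
                                            call. = FALSE)
  lab <- phantom_labels(spec)
  paren <- lab == 2L | lab == 3L
  d <- spec$shape
  vox_mm <- mean(spec$voxel_size_mm)
  # lesion placement uses its own seed stream so that the subject's noise
  # field is the same one a control with this subject_seed would get
  res <- with_seed(child_seed(spec$seed + 1000003, subject_seed), {
    lesion <- array(FALSE, d)
    rows <- list()
    if (lesions$count > 0) {
      paren_idx <- which(paren)
      for (li in seq_len(lesions$count)) {
        r_mm <- stats::runif(1, lesions$radius_mm[1], lesions$radius_mm[2])
        r_vox <- r_mm / vox_mm
        dec <- stats::runif(1, lesions$decrement_hu[1],
                            lesions$decrement_hu[2])
        placed <- FALSE
        for (try in 1:200) {
          ctr_lin <- sample(paren_idx, 1)
          ctr <- arrayInd(ctr_lin, d)[1, ]
          sph <- sphere_mask(d, ctr, r_vox)
          if (all(paren[sph])) { placed <- TRUE; break }
        }
        if (!placed)
          stop("no parenchyma room for a lesion of radius ", round(r_mm, 1),
               " mm", call. = FALSE)
        les_i <- sph
        rows[[length(rows) + 1]] <- data.frame(
          lesion = li, sphere = 1L, x = ctr[1], y = ctr[2], z = ctr[3],
          radius_vox = r_vox, decrement_hu = dec)
        if (lesions$n_spheres > 1) for (si in 2:lesions$n_spheres) {
          off <- stats::runif(3, -0.5, 0.5) * r_vox
          sctr <- ctr + off
          sr <- 0.6 * r_vox
          ssph <- sphere_mask(d, sctr, sr)
          if (!all(paren[ssph])) next # satellite must stay in parenchyma
          les_i <- les_i | ssph
          rows[[length(rows) + 1]] <- data.frame(
            lesion = li, sphere = si, x = sctr[1], y = sctr[2],
            z = sctr[3], radius_vox = sr, decrement_hu = dec)
        }
        lesion <- lesion | les_i
      }
    }
    list(lesion = lesion, rows = rows)
  })
  vol <- with_seed(child_seed(spec$seed, subject_seed),
                   phantom_hu_from_labels(spec, lab))
  meta <- if (length(res$rows)) do.call(rbind, res$rows) else
    data.frame(lesion = integer(), sphere = integer(), x = numeric(),
               y = numeric(), z = numeric(), radius_vox = numeric(),
               decrement_hu = numeric())
  if (any(res$lesion)) {
    for (li in unique(meta$lesion)) {
      sub <- meta[meta$lesion == li, ]
      m <- array(FALSE, d)
      for (si in seq_len(nrow(sub)))
        m <- m | sphere_mask(d, c(sub$x[si], sub$y[si], sub$z[si]),
                             sub$radius_vox[si])
      vol[m] <- vol[m] - sub$decrement_hu[1]
    }
  } else if (lesions$count > 0) {
    stop("lesion mask is empty", call. = FALSE)
  }
  list(
    volume = ct_volume(vol, voxel_size_mm = spec$voxel_size_mm,
                       space = "template", unit = "HU"),
    lesion_mask = binary_mask(res$lesion, "lesion"),
    lesions = meta
  )
}

#' Generate a full phantom cohort on disk
#'
#' Writes one NIfTI volume per control, one volume plus one ground-truth
#' lesion mask per patient, and a manifest CSV. Default cohort sizes are 38
#' controls and 21 patients. Fully reproducible from `seed`.
#'
#' @param dir output directory.
#' @param n_controls,n_patients cohort sizes (`n_controls >= 2`).
#' @param spec a [phantom_spec()]; its `seed` field is replaced by `seed`.
#' @param lesions a [lesion_spec()].
#' @param seed cohort seed.
#' @return The manifest as a data frame (also written to
#'   `<dir>/manifest.csv`): subject id, role, seed, file paths, lesion
#'   voxel count.
#' @export
generate_cohort <- function(dir, n_controls = 38, n_patients = 21,
                            spec = phantom_spec(), lesions = lesion_spec(),
                            seed = 0L) {
  if (n_controls < 2) stop("need at least two controls", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec$seed <- as.integer(seed)
  rows <- list()
  for (i in seq_len(n_controls)) {
    v <- generate_control(spec, subject_seed = i)
    f <- file.path(dir, sprintf("control_%02d.nii.gz", i))
    write_volume(v, f)
    rows[[length(rows) + 1]] <- data.frame(
      subject = sprintf("control_%02d", i), role = "control",
      subject_seed = i, volume = f, lesion_mask = NA_character_,
      lesion_voxels = 0L)
  }
  for (i in seq_len(n_patients)) {
    ss <- n_controls + i
    p <- generate_patient(spec, lesions, subject_seed = ss)
    f <- file.path(dir, sprintf("patient_%02d.nii.gz", i))
    fm <- file.path(dir, sprintf("patient_%02d_lesion.nii.gz", i))
    write_volume(p$volume, f)
    write_volume(p$lesion_mask, fm)
    rows[[length(rows) + 1]] <- data.frame(
      subject = sprintf("patient_%02d", i), role = "patient",
      subject_seed = ss, volume = f, lesion_mask = fm,
      lesion_voxels = sum(p$lesion_mask$data))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Sulcus groove geometry
#'
#' A fluid-filled groove carved into the lateral brain surface, used to
#' reproduce qualitatively the false-positive mechanism where an ageing
#' sulcus mimics an infarct: the groove voxels take CSF-like intensities,
#' which after preprocessing sit far below the control mean at the same
#' coordinates.
#'
#' @param center_yz coronal/axial voxel coordinates of the groove axis.
#' @param radius_mm groove radius perpendicular to the sagittal axis.
#' @param depth_mm how deep the groove cuts inward from the brain surface.
#' @param side `"+x"` or `"-x"`: which lateral surface is carved.
#' @return An object of class `sulcus_spec`.
#' @export
sulcus_spec <- function(center_yz, radius_mm = 6, depth_mm = 12,
                        side = "+x") {
  structure(list(center_yz = as.numeric(center_yz),
                 radius_mm = radius_mm, depth_mm = depth_mm,
                 side = match.arg(side, c("+x", "-x"))),
            class = "sulcus_spec")
}

#' Carve a CSF-filled sulcus groove into a phantom
#'
#' For every in-plane position within the groove radius, the brain surface
#' is located from the chosen lateral side (skipping skull) and the tissue
#' is replaced by CSF-level HU plus noise down to `depth_mm`. A groove
#' whose footprint meets no brain tissue is an error; a zero-size groove is
#' the identity.
#'
#' @param vol a [ct_volume()] in HU.
#' @param spec a [sulcus_spec()].
#' @param noise_sd noise SD of the fluid voxels (HU).
#' @param seed RNG seed for the groove noise.
#' @return The modified [ct_volume()].
#' @export
add_sulcus_artifact <- function(vol, spec, noise_sd = 3, seed = 0L) {
  stopifnot_unit(vol, "HU")
  if (!inherits(spec, "sulcus_spec")) stop("`spec` must be a sulcus_spec",
                                           call. = FALSE)
  if (spec$radius_mm <= 0 || spec$depth_mm <= 0) return(vol)
  d <- dim(vol$data)
  vox <- vol$voxel_size_mm
  r_y <- spec$radius_mm / vox[2]
  r_z <- spec$radius_mm / vox[3]
  depth <- max(1L, round(spec$depth_mm / vox[1]))
  cy <- spec$center_yz[1]; cz <- spec$center_yz[2]
  ys <- seq_len(d[2]); zs <- seq_len(d[3])
  groove <- array(FALSE, d)
  brainish <- vol$data > -200 & vol$data < 500 # tissue/CSF, not air or bone
  for (y in ys[abs(ys - cy) <= r_y]) for (z in zs[abs(zs - cz) <= r_z]) {
    if (((y - cy) / r_y)^2 + ((z - cz) / r_z)^2 > 1) next
    col <- brainish[, y, z]
    if (!any(col)) next
    surf <- if (spec$side == "+x") max(which(col)) else min(which(col))
    xs <- if (spec$side == "+x") seq(surf, by = -1L, length.out = depth)
          else seq(surf, by = 1L, length.out = depth)
    xs <- xs[xs >= 1 & xs <= d[1]]
    groove[xs, y, z] <- TRUE
  }
  if (!any(groove))
    stop("groove does not intersect the brain surface", call. = FALSE)
  out <- vol
  out$data[groove] <- with_seed(seed,
    stats::rnorm(sum(groove), 0, noise_sd))
  out
}
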