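test_that("tiling a fully-masked slice produces the exact complete-tile
           grid", {
  t32 <- array(rnorm(32 * 32), c(32, 32, 1))
  ps <- tile_patches(make_tmap(t32))
  expect_length(ps, 4)
  corners <- t(sapply(ps, function(p) c(p$row0, p$col0)))
  expect_setequal(paste(corners[, 1], corners[, 2]),
                  c("0 0", "0 16", "16 0", "16 16"))
  p <- ps[[which(corners[, 1] == 16 & corners[, 2] == 0)]]
  expect_equal(p$values, t32[17:32, 1:16, 1])
})

test_that("a full template slice yields 143 complete tiles; the area
           estimate is 153", {
  tt <- array(0, c(181, 217, 1))
  ps <- tile_patches(make_tmap(tt))
  expect_length(ps, floor(181 / 16) * floor(217 / 16))
  expect_length(ps, 143)
  expect_equal(slice_patch_estimate(181, 217, 16), 153L)
})

test_that("tile footprints are disjoint and strictly inside the mask", {
  set.seed(21)
  # mostly-true mask with a few punched-out rectangles
  m <- array(TRUE, c(64, 64, 2))
  for (i in 1:6) {
    r <- sample(1:52, 1); c_ <- sample(1:52, 1); k <- sample(0:2, 1)
    m[r:(r + 9), c_:(c_ + 9), k + 1] <- FALSE
  }
  tm <- make_tmap(array(rnorm(64 * 64 * 2), c(64, 64, 2)), m)
  ps <- tile_patches(tm)
  seen <- array(FALSE, dim(m))
  expect_gt(length(ps), 0)
  for (p in ps) {
    idx <- seq_len(16)
    block <- m[p$row0 + idx, p$col0 + idx, p$slice + 1]
    expect_true(all(block))
    expect_false(any(seen[p$row0 + idx, p$col0 + idx, p$slice + 1]))
    seen[p$row0 + idx, p$col0 + idx, p$slice + 1] <- TRUE
  }
  # masking out one pixel of an adopted tile removes exactly that tile
  if (length(ps) > 0) {
    p <- ps[[1]]
    m2 <- m
    m2[p$row0 + 1, p$col0 + 1, p$slice + 1] <- FALSE
    ps2 <- tile_patches(make_tmap(tm$t, m2))
    expect_length(ps2, length(ps) - 1)
  }
})

test_that("patch size larger than the slice yields no patches", {
  expect_length(tile_patches(make_tmap(array(0, c(8, 8, 1))), 16), 0)
})

test_that("labeling thresholds follow overlap counts", {
  lm <- array(FALSE, c(32, 32, 1))
  lm[1, 1, 1] <- TRUE
  p <- ct_patch(matrix(0, 16, 16), 0, 0, 0)
  expect_identical(label_patch(p, binary_mask(lm, "lesion"))$label,
                   "infarcted")
  expect_identical(label_patch(p, binary_mask(lm, "lesion"),
                               min_lesion_pixels = 2)$label,
                   "non_infarcted")
  lm2 <- array(FALSE, c(32, 32, 1))
  lm2[1:5, 1:5, 1] <- TRUE # 25 overlapping pixels
  expect_identical(label_patch(p, binary_mask(lm2, "lesion"),
                               min_lesion_pixels = 26)$label,
                   "non_infarcted")
  expect_identical(label_patch(p, binary_mask(lm2, "lesion"),
                               min_lesion_pixels = 25)$label, "infarcted")
  lm0 <- array(FALSE, c(32, 32, 1))
  expect_identical(label_patch(p, binary_mask(lm0, "lesion"))$label,
                   "non_infarcted")
})

test_that("augmentation adopts all 8 shifts deep inside a uniform lesion",
{
  d <- c(64, 64, 1)
  tm <- make_tmap(array(rnorm(prod(d)), d))
  les <- binary_mask(array(TRUE, d), "lesion")
  p <- label_patch(ct_patch(tm$t[25:40, 25:40, 1], 0, 24, 24), les)
  aug <- augment_patch(p, tm, les)
  expect_length(aug, 8)
  expect_setequal(sapply(aug, function(a) a$provenance),
                  paste0("augmented:", c("N", "NE", "E", "SE", "S", "SW",
                                         "W", "NW")))
  expect_true(all(sapply(aug, function(a) a$label) == "infarcted"))
  # shifted values come from the right place
  east <- aug[[which(sapply(aug, function(a)
    a$provenance == "augmented:E"))]]
  expect_equal(east$values, tm$t[25:40, 29:44, 1])
})

test_that("masked east column rejects the three eastward shifts", {
  d <- c(64, 64, 1)
  m <- array(TRUE, d)
  m[, 44, 1] <- FALSE # last column of an E/NE/SE shift by 4 (cols 29..44)
  tm <- make_tmap(array(rnorm(prod(d)), d), m)
  les <- binary_mask(array(FALSE, d), "lesion")
  p <- label_patch(ct_patch(tm$t[25:40, 25:40, 1], 0, 24, 24), les)
  aug <- augment_patch(p, tm, les)
  dirs <- sapply(aug, function(a) sub("augmented:", "", a$provenance))
  expect_false(any(dirs %in% c("E", "NE", "SE")))
  expect_setequal(dirs, c("N", "S", "W", "NW", "SW"))
})

test_that("a label-flipping shift is rejected", {
  d <- c(64, 64, 1)
  tm <- make_tmap(array(rnorm(prod(d)), d))
  les <- array(FALSE, d)
  les[21:24, 25:40, 1] <- TRUE # within reach of a 4-pixel northward shift
  lesm <- binary_mask(les, "lesion")
  p <- label_patch(ct_patch(tm$t[25:40, 25:40, 1], 0, 24, 24), lesm)
  expect_identical(p$label, "non_infarcted")
  aug <- augment_patch(p, tm, lesm)
  dirs <- sapply(aug, function(a) sub("augmented:", "", a$provenance))
  expect_false(any(dirs %in% c("N", "NE", "NW")))
})

test_that("augmentation matches the exhaustive rule-checking oracle on
           randomized placements", {
  set.seed(33)
  d <- c(48, 48, 3)
  checked <- 0
  attempts <- 0
  while (checked < 110 && attempts < 3000) {
    attempts <- attempts + 1
    # mostly-true mask with punched rectangles; rectangular lesions
    m <- array(TRUE, d)
    les <- array(FALSE, d)
    for (i in 1:3) {
      r <- sample(1:38, 1); c_ <- sample(1:38, 1); k <- sample(1:3, 1)
      m[r:(r + 9), c_:(c_ + 9), k] <- FALSE
    }
    for (i in 1:2) {
      r <- sample(1:36, 1); c_ <- sample(1:36, 1); k <- sample(1:3, 1)
      les[r:(r + 11), c_:(c_ + 11), k] <- TRUE
    }
    tm <- make_tmap(array(rnorm(prod(d)), d), m)
    lesm <- binary_mask(les, "lesion")
    sl <- sample(0:2, 1)
    r0 <- sample(0:(d[1] - 16), 1)
    c0 <- sample(0:(d[2] - 16), 1)
    if (!all(m[r0 + 1:16, c0 + 1:16, sl + 1])) next # not an adopted tile
    p <- label_patch(ct_patch(tm$t[r0 + 1:16, c0 + 1:16, sl + 1],
                              sl, r0, c0), lesm)
    got <- sapply(augment_patch(p, tm, lesm),
                  function(a) sub("augmented:", "", a$provenance))
    want <- oracle_augment(m, les, sl, r0, c0, 16, 4)
    expect_setequal(as.character(got), want)
    checked <- checked + 1
  }
  expect_gte(checked, 100)
})

test_that("class balancing reproduces the reference cohort arithmetic and
           is order-invariant", {
  mk <- function(lab, n, offset = 0) lapply(seq_len(n), function(i)
    ct_patch(matrix(0, 4, 4), slice = i + offset, row0 = 0, col0 = 0,
             label = lab, subject = sprintf("%s%05d", lab, i)))
  # ratio 1.064 on 2656 infarcted keeps 2826 non-infarcted: total 5482
  pool <- c(mk("infarcted", 2656), mk("non_infarcted", 4000, 10000))
  ds <- balance_classes(pool, seed = 99, max_ratio = 1.064)
  expect_equal(unname(ds$class_counts["infarcted"]), 2656)
  expect_equal(unname(ds$class_counts["non_infarcted"]), 2826)
  expect_equal(length(ds$patches), 5482)
  # exact 1:1 balancing
  ds1 <- balance_classes(c(mk("infarcted", 100),
                           mk("non_infarcted", 1000, 10000)),
                         seed = 1, max_ratio = 1.0)
  expect_equal(unname(ds1$class_counts), c(100, 100))
  # determinism and input-order invariance
  shuffled <- sample(pool)
  ds2 <- balance_classes(shuffled, seed = 99, max_ratio = 1.064)
  key <- function(x) sapply(x$patches, function(p)
    paste(p$subject, p$slice, p$row0, p$col0))
  expect_identical(key(ds), key(ds2))
  expect_error(balance_classes(mk("infarcted", 5), seed = 1),
               "both classes")
})

test_that("the 80/20 split reproduces the reference counts and rounding",
{
  mk <- function(n) lapply(seq_len(n), function(i)
    ct_patch(matrix(0, 4, 4), slice = i, row0 = 0, col0 = 0,
             label = if (i %% 2 == 0) "infarcted" else "non_infarcted",
             subject = sprintf("s%05d", i)))
  ds <- split_dataset(patch_dataset(mk(5482)), 0.8, seed = 4)
  expect_equal(sum(ds$split == "train"), 4386)
  expect_equal(sum(ds$split == "validation"), 1096)
  expect_equal(sum(split_dataset(patch_dataset(mk(10)), 0.8,
                                 seed = 1)$split == "train"), 8)
  expect_equal(sum(split_dataset(patch_dataset(mk(5)), 0.8,
                                 seed = 1)$split == "train"), 4)
  # same seed, same assignment; different seed resamples
  a <- split_dataset(patch_dataset(mk(100)), 0.8, seed = 5)
  b <- split_dataset(patch_dataset(mk(100)), 0.8, seed = 5)
  c_ <- split_dataset(patch_dataset(mk(100)), 0.8, seed = 6)
  expect_identical(a$split, b$split)
  expect_false(identical(a$split, c_$split))
  expect_error(split_dataset(patch_dataset(list()), 0.8, 1), "empty")
})

test_that("patch datasets round-trip through the manifest serialization", {
  set.seed(12)
  mk <- lapply(1:20, function(i)
    ct_patch(matrix(rnorm(256), 16, 16), slice = i %% 3, row0 = 16 * i,
             col0 = 0, label = if (i %% 2 == 0) "infarcted"
             else "non_infarcted", subject = sprintf("s%02d", i)))
  ds <- split_dataset(patch_dataset(mk, seed = 2), 0.8, seed = 3)
  dir <- tempfile()
  write_patch_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_patch_dataset(dir)
  expect_equal(length(back$patches), 20)
  expect_identical(sapply(back$patches, `[[`, "label"),
                   sapply(ds$patches, `[[`, "label"))
  expect_equal(back$patches[[5]]$values, ds$patches[[5]]$values,
               tolerance = 1e-12)
  expect_identical(back$split, ds$split)
})
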