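# A small but complete pipeline fixture: tiny phantoms, a handful of
# controls, a briefly trained classifier. Built once per test file.
detect_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- tiny_spec()
    controls <- lapply(1:8, function(i) generate_control(spec, i))
    fit <- fit_normative_cohort(controls)
    les <- lesion_spec(count = 2, radius_mm = c(16, 20),
                       decrement_hu = c(15, 20), n_spheres = 1)
    patient <- generate_patient(spec, les, subject_seed = 30)
    patches <- list()
    for (i in 1:8) {
      tm <- compute_tscore_map(fit$preprocessed[[i]], fit$model,
                               fit$segmentations[[i]]$parenchyma_mask)
      patches <- c(patches, harvest_patches(tm, sprintf("c%02d", i)))
    }
    pre <- preprocess_ct(patient$volume)
    tm_p <- compute_tscore_map(pre$volume, fit$model,
                               pre$segmentation$parenchyma_mask)
    patches <- c(patches, harvest_patches(tm_p, "p01",
                                          lesion_mask = patient$lesion_mask,
                                          augment = TRUE))
    ds <- balance_classes(patches, seed = 5)
    ds <- split_dataset(ds, 0.8, seed = 6)
    # constant learning rate: this fixture tests detection mechanics, so
    # train to convergence rather than emulate any particular budget
    cnn <- train_cnn(build_cnn(seed = 7), ds,
                     train_config(lr_initial = 1e-5, lr_final = 1e-5,
                                  max_iterations = 1200, batch_size = 100,
                                  seed = 8))
    cache <<- list(spec = spec, fit = fit, controls = controls,
                   patient = patient, cnn = cnn)
    cache
  }
})

test_that("end-to-end detection finds the planted lesion and is
           deterministic", {
  fx <- detect_fixture()
  det <- detect_infarcts(fx$patient$volume, fx$cnn, fx$fit$model,
                         patient_id = "p01")
  expect_gt(det$n_tiles, 0)
  expect_true(all(det$detections$probability >= 0 &
                    det$detections$probability <= 1))
  # detections are a subset of adopted tiles
  key <- function(df) paste(df$slice, df$row0, df$col0)
  expect_true(all(key(det$detections) %in% key(det$tiles)))
  # the lesion is hit: most lesion-overlapping tiles are flagged
  lm <- fx$patient$lesion_mask$data
  tl <- det$tiles
  truth <- vapply(seq_len(nrow(tl)), function(j) {
    idx <- seq_len(det$patch_size)
    sum(lm[tl$row0[j] + idx, tl$col0[j] + idx, tl$slice[j] + 1]) >= 1
  }, TRUE)
  expect_gt(sum(truth), 0)
  expect_gt(mean(tl$label[truth] == "infarcted"), 0.5)
  det2 <- detect_infarcts(fx$patient$volume, fx$cnn, fx$fit$model,
                          patient_id = "p01")
  expect_identical(det$detections, det2$detections)
})

test_that("a lesion-free cohort member yields few detections", {
  fx <- detect_fixture()
  det <- detect_infarcts(fx$controls[[2]], fx$cnn, fx$fit$model,
                         patient_id = "ctl")
  expect_lt(nrow(det$detections) / det$n_tiles, 0.25)
})

test_that("atlas lookup returns overlapped labels sorted by pixel count",
{
  lab <- array(0L, c(32, 32, 2))
  lab[1:16, 1:16, 1] <- 25L
  atlas1 <- list(labels = lab,
                 names = data.frame(label = 25L, name = "INSULAR"))
  hit <- map_patch_to_atlas(0, 0, 0, atlas1)
  expect_equal(hit$label, 25L)
  expect_equal(hit$name, "INSULAR")
  expect_equal(hit$n_pixels, 256L)

  # four-label footprint mirroring a deep MCA-territory patch
  lab4 <- array(0L, c(32, 32, 1))
  lab4[1:10, 1:16, 1] <- 25L
  lab4[11:16, 1:8, 1] <- 47L
  lab4[11:14, 9:16, 1] <- 60L
  lab4[15:16, 9:16, 1] <- 62L
  atlas4 <- list(labels = lab4,
                 names = data.frame(label = c(25L, 47L, 60L, 62L),
                                    name = c("INSULAR",
                                             "External_capsule_left",
                                             "PUTAMEN_left",
                                             "GLOBUS_PALLIDUS_left")))
  hit4 <- map_patch_to_atlas(0, 0, 0, atlas4)
  expect_setequal(hit4$label, c(25L, 47L, 60L, 62L))
  expect_true(all(diff(hit4$n_pixels) <= 0))
  expect_equal(sum(hit4$n_pixels), 256L)

  # background-only footprint
  none <- map_patch_to_atlas(0, 16, 16, atlas1)
  expect_equal(nrow(none), 0)
  expect_error(map_patch_to_atlas(0, 20, 20, atlas1), "outside")
})

test_that("localized detections carry their atlas regions", {
  fx <- detect_fixture()
  det <- detect_infarcts(fx$patient$volume, fx$cnn, fx$fit$model)
  lab <- array(1L, dim(fx$patient$volume$data))
  res <- localize_detections(det, list(labels = lab,
                                       names = data.frame(label = 1L,
                                                          name = "brain")))
  if (nrow(res$detections) > 0)
    expect_equal(res$detections$regions[[1]]$name, "brain")
})

test_that("report rendering writes overlays, CSV and JSON that round-trip",
{
  fx <- detect_fixture()
  det <- detect_infarcts(fx$patient$volume, fx$cnn, fx$fit$model,
                         patient_id = "p01")
  dir <- tempfile()
  files <- render_report(det, fx$patient$volume, dir)
  expect_true(file.exists(file.path(dir, "p01_detections.csv")))
  js <- jsonlite::read_json(file.path(dir, "p01_summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$n_detected, nrow(det$detections))
  expect_equal(js$n_tiles, det$n_tiles)
  if (nrow(det$detections) > 0) {
    sl <- det$detections$slice[1]
    f <- file.path(dir, sprintf("p01_slice%03d.png", sl))
    expect_true(file.exists(f))
    img <- png::readPNG(f)
    expect_true(any(img[, , 1] == 1 & img[, , 2] == 0)) # red box drawn
  }
})

test_that("zero detections produce an empty table and no overlays", {
  fx <- detect_fixture()
  empty <- structure(
    list(patient_id = "none",
         detections = data.frame(slice = integer(), row0 = integer(),
                                 col0 = integer(),
                                 probability = numeric()),
         tiles = NULL, n_tiles = 0, patch_size = 16,
         shape = dim(fx$patient$volume$data), tscore_map = NULL),
    class = "infarct_detection")
  dir <- tempfile()
  files <- render_report(empty, fx$patient$volume, dir)
  expect_length(list.files(dir, pattern = "png$"), 0)
  tab <- read.csv(file.path(dir, "none_detections.csv"))
  expect_equal(nrow(tab), 0)
})
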