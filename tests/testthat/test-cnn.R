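make_sep_dataset <- function(n_per_class, mu = 3, seed = 1) {
  set.seed(seed)
  mk <- function(m, n, lab) lapply(seq_len(n), function(i)
    ct_patch(matrix(rnorm(256, m, 1), 16, 16), slice = i, row0 = 0,
             col0 = 0, label = lab, subject = sprintf("%s%04d", lab, i)))
  patch_dataset(c(mk(-mu, n_per_class, "infarcted"),
                  mk(mu, n_per_class, "non_infarcted")), seed = seed)
}

test_that("the default architecture enumerates 17 layers and halves the
           grid three times", {
  m <- build_cnn(seed = 1)
  expect_length(cnn_layers(m), 17)
  expect_equal(sum(cnn_layers(m) == "convolution"), 3)
  expect_equal(sum(cnn_layers(m) == "batch_normalization"), 3)
  expect_equal(sum(cnn_layers(m) == "relu"), 3)
  expect_equal(sum(cnn_layers(m) == "max_pooling"), 3)
  # 16 -> 8 -> 4 -> 2 spatial size means 2*2*32 features into the FC layer
  expect_equal(nrow(m$params$fc$W), 2 * 2 * 32)
  expect_equal(ncol(m$params$fc$W), 2)
  expect_error(cnn_config(input_size = 12), "divisible")
})

test_that("forward pass produces probabilities summing to one", {
  m <- build_cnn(seed = 2)
  set.seed(4)
  x <- array(rnorm(16 * 16 * 7), c(16, 16, 7))
  fw <- infarctCT:::cnn_forward(m, x, training = FALSE)
  expect_equal(rowSums(fw$probs), rep(1, 7), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0))
  # all-zero input still yields a valid probability vector
  fw0 <- infarctCT:::cnn_forward(m, array(0, c(16, 16, 1)),
                                 training = FALSE)
  expect_equal(sum(fw0$probs), 1, tolerance = 1e-6)
})

test_that("training overfits small separable data and logs the schedule",
{
  ds <- split_dataset(make_sep_dataset(10), 0.8, seed = 2)
  tc <- train_config(max_iterations = 2000, batch_size = 10, seed = 3)
  m <- train_cnn(build_cnn(seed = 1), ds, tc)
  expect_true(m$trained)
  pred <- predict_patches(m, ds$patches[ds$split == "train"])
  truth <- sapply(ds$patches[ds$split == "train"], `[[`, "label")
  expect_equal(mean(pred$label == truth), 1)
  # geometric schedule endpoints
  h <- m$history
  expect_equal(h$lr[1], 1e-5, tolerance = 1e-8)
  expect_equal(h$lr[nrow(h)], 1e-7, tolerance = 1e-9)
  # loss trend decreases on separable data (smoothed window comparison)
  k <- nrow(h) %/% 3
  expect_lt(mean(tail(h$loss, k)), mean(head(h$loss, k)))
})

test_that("epoch arithmetic: 4386 training patches at batch 500 give 9
           updates per epoch so the iteration cap binds", {
  n <- 4386; batch <- 500
  steps <- ceiling(n / batch)
  expect_equal(steps, 9)
  planned <- min(1000, ceiling(8000 / steps))
  expect_equal(planned, 889) # < 1000: the 8000-iteration cap binds first
})

test_that("training requires a split and both classes", {
  ds <- make_sep_dataset(5)
  expect_error(train_cnn(build_cnn(), ds, train_config()), "split")
  one <- patch_dataset(lapply(1:10, function(i)
    ct_patch(matrix(0, 16, 16), i, 0, 0, label = "infarcted",
             subject = sprintf("s%d", i))))
  one <- split_dataset(one, 0.8, 1)
  expect_error(train_cnn(build_cnn(), one, train_config()), "both classes")
})

test_that("inference is deterministic and reproducible; untrained models
           are rejected", {
  ds <- split_dataset(make_sep_dataset(10), 0.8, seed = 2)
  m <- train_cnn(build_cnn(seed = 1), ds,
                 train_config(max_iterations = 30, batch_size = 8,
                              seed = 3))
  p1 <- predict_patches(m, ds$patches[1:5])
  p2 <- predict_patches(m, ds$patches[1:5])
  expect_identical(p1, p2)
  expect_error(predict_patches(build_cnn(), ds$patches[1:5]),
               "not been trained")
  # seeded training is bitwise reproducible
  m2 <- train_cnn(build_cnn(seed = 1), ds,
                  train_config(max_iterations = 30, batch_size = 8,
                               seed = 3))
  expect_identical(m$params, m2$params)
})

test_that("checkpoints round-trip through save/load", {
  ds <- split_dataset(make_sep_dataset(6), 0.8, seed = 2)
  m <- train_cnn(build_cnn(seed = 5), ds,
                 train_config(max_iterations = 10, batch_size = 4,
                              seed = 6))
  f <- tempfile(fileext = ".rds")
  save_cnn(m, f)
  m2 <- load_cnn(f)
  expect_identical(predict_patches(m, ds$patches[1:3]),
                   predict_patches(m2, ds$patches[1:3]))
})

test_that("metrics reproduce the reference confusion-matrix arithmetic",
{
  # test-set column of the reference confusion table, in percent
  test_cm <- confusion_matrix(TP = 46.26, FN = 0.73, FP = 5.38, TN = 47.63)
  mt <- compute_metrics(test_cm)
  expect_equal(infarctCT:::round_half_up(mt$accuracy, 1), 93.9)
  expect_equal(infarctCT:::round_half_up(mt$sensitivity, 1), 98.4)
  # training-set column
  train_cm <- confusion_matrix(TP = 46.81, FN = 0.87, FP = 4.72,
                               TN = 47.61)
  mtr <- compute_metrics(train_cm)
  expect_equal(infarctCT:::round_half_up(mtr$accuracy, 1), 94.4)
  expect_equal(infarctCT:::round_half_up(mtr$sensitivity, 1), 98.2)
  expect_equal(infarctCT:::round_half_up(mtr$specificity, 1), 91.0)
})

test_that("metrics are scale-invariant and handle degenerate cases", {
  a <- compute_metrics(confusion_matrix(46.26, 0.73, 5.38, 47.63))
  b <- compute_metrics(confusion_matrix(4626, 73, 538, 4763))
  expect_equal(a$accuracy, b$accuracy, tolerance = 1e-12)
  expect_equal(a$sensitivity, b$sensitivity, tolerance = 1e-12)
  expect_equal(a$specificity, b$specificity, tolerance = 1e-12)
  perfect <- compute_metrics(confusion_matrix(1, 0, 0, 1))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_error(confusion_matrix(0, 0, 0, 0), "not all zero")
  expect_error(confusion_matrix(-1, 0, 0, 1), "nonnegative")
})

test_that("confusion tabulation from labels matches manual counts", {
  truth <- c("infarcted", "infarcted", "non_infarcted", "non_infarcted",
             "non_infarcted")
  pred <- c("infarcted", "non_infarcted", "infarcted", "non_infarcted",
            "non_infarcted")
  cm <- confusion_from_labels(truth, pred)
  expect_equal(cm$TP, 1)
  expect_equal(cm$FN, 1)
  expect_equal(cm$FP, 1)
  expect_equal(cm$TN, 2)
})
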