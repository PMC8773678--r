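#' Configuration of the 17-layer patch classifier
#'
#' Three convolution blocks (convolution, batch normalization, rectified
#' linear unit, 2x2 max pooling) followed by a fully connected layer to two
#' classes, dropout, softmax, and the classification (cross-entropy) output.
#' Counting the input layer, the enumeration is 17 layers. Kernel size,
#' filter counts and dropout placement are configurable; the defaults are
#' 3x3 kernels with stride 1 and symmetric padding, filters (8, 16, 32),
#' and dropout applied after the fully connected layer.
#'
#' @param input_size patch edge length (default 16).
#' @param conv_filters integer triple of filters per block.
#' @param kernel odd kernel edge length (default 3).
#' @param n_class number of output classes (default 2).
#' @param dropout dropout rate (default 0.5).
#' @param dropout_position `"after_fc"` (default) or `"before_fc"`.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(input_size = 16, conv_filters = c(8, 16, 32),
                       kernel = 3, n_class = 2, dropout = 0.5,
                       dropout_position = "after_fc") {
  if (kernel %% 2 != 1) stop("`kernel` must be odd", call. = FALSE)
  if (length(conv_filters) != 3)
    stop("`conv_filters` must have three entries", call. = FALSE)
  if (input_size %% 8 != 0)
    stop("`input_size` must be divisible by 8 (three 2x2 pooling stages)",
         call. = FALSE)
  structure(
    list(input_size = as.integer(input_size),
         conv_filters = as.integer(conv_filters),
         kernel = as.integer(kernel), n_class = as.integer(n_class),
         dropout = dropout,
         dropout_position = match.arg(dropout_position,
                                      c("after_fc", "before_fc"))),
    class = "cnn_config"
  )
}

#' Training configuration (SGDM)
#'
#' Stochastic gradient descent with momentum, cross-entropy loss, and a
#' geometric learning-rate decay from `lr_initial` at the first epoch to
#' `lr_final` at the last planned epoch. The planned run length is
#' `min(max_epochs, ceiling(max_iterations / steps_per_epoch))`; whichever
#' cap binds first stops training. L2 weight decay applies to convolution
#' and fully connected weights.
#'
#' @param lr_initial,lr_final initial/final learning rates (defaults 1e-5,
#'   1e-7).
#' @param momentum momentum coefficient (default 0.9).
#' @param max_epochs epoch cap (default 1000).
#' @param max_iterations weight-update cap (default 8000).
#' @param batch_size mini-batch size (default 500; partial final batches
#'   are used).
#' @param weight_decay L2 penalty coefficient (default 0.005).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr_initial = 1e-5, lr_final = 1e-7,
                         momentum = 0.9, max_epochs = 1000,
                         max_iterations = 8000, batch_size = 500,
                         weight_decay = 0.005, seed = 1L) {
  if (lr_final > lr_initial)
    stop("`lr_final` must not exceed `lr_initial`", call. = FALSE)
  if (lr_initial <= 0 || lr_final <= 0 || momentum < 0 || momentum >= 1)
    stop("invalid optimizer rates", call. = FALSE)
  structure(
    list(lr_initial = lr_initial, lr_final = lr_final, momentum = momentum,
         max_epochs = as.integer(max_epochs),
         max_iterations = as.integer(max_iterations),
         batch_size = as.integer(batch_size), weight_decay = weight_decay,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Build an (untrained) patch classifier
#'
#' Convolution and fully connected weights use He-normal initialization;
#' batch-norm scale/shift start at 1/0. The model maps a 16 x 16 t-score
#' matrix to a two-class probability vector.
#'
#' @param cfg a [cnn_config()].
#' @param seed seed for weight initialization.
#' @return An object of class `infarct_cnn`.
#' @export
build_cnn <- function(cfg = cnn_config(), seed = 1L) {
  if (!inherits(cfg, "cnn_config")) stop("`cfg` must be a cnn_config",
                                         call. = FALSE)
  k <- cfg$kernel
  chans <- c(1L, cfg$conv_filters)
  feat <- as.integer((cfg$input_size / 8)^2 * cfg$conv_filters[3])
  params <- with_seed(seed, {
    p <- list()
    for (i in 1:3) {
      fan_in <- k * k * chans[i]
      p[[paste0("conv", i)]] <- list(
        W = array(stats::rnorm(k * k * chans[i] * chans[i + 1],
                               sd = sqrt(2 / fan_in)),
                  c(k, k, chans[i], chans[i + 1])),
        b = numeric(chans[i + 1]))
      p[[paste0("bn", i)]] <- list(
        gamma = rep(1, chans[i + 1]), beta = numeric(chans[i + 1]),
        run_mean = numeric(chans[i + 1]), run_var = rep(1, chans[i + 1]))
    }
    p$fc <- list(W = matrix(stats::rnorm(feat * cfg$n_class,
                                         sd = sqrt(2 / feat)),
                            feat, cfg$n_class),
                 b = numeric(cfg$n_class))
    p
  })
  structure(
    list(cfg = cfg, params = params, classes = c("infarcted",
                                                 "non_infarcted"),
         trained = FALSE, history = NULL, seed = as.integer(seed)),
    class = "infarct_cnn"
  )
}

#' Enumerate the classifier's layers
#'
#' @param model an `infarct_cnn`.
#' @return Character vector naming each layer in order (length 17 for the
#'   default architecture).
#' @export
cnn_layers <- function(model) {
  c("input",
    rep(c("convolution", "batch_normalization", "relu", "max_pooling"), 3),
    "fully_connected", "dropout", "softmax", "classification")
}

#' @export
print.infarct_cnn <- function(x, ...) {
  cat(sprintf("<infarct_cnn> %d layers, input %dx%d, filters (%s), %s\n",
              length(cnn_layers(x)), x$cfg$input_size, x$cfg$input_size,
              paste(x$cfg$conv_filters, collapse = ", "),
              if (x$trained) "trained" else "untrained"))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d iterations (%d epochs), final loss %.4f%s\n",
                last$iteration, last$epoch, last$loss,
                if (!is.na(last$val_accuracy))
                  sprintf(", val accuracy %.1f%%", last$val_accuracy)
                else ""))
  }
  invisible(x)
}

# ---- layer primitives (fc, dropout, softmax in R; conv, pool and fused
#      batch-norm+relu in compiled code) ----

fc_forward <- function(x, p) {
  d <- dim(x)
  f <- aperm(x, c(1, 2, 4, 3))
  dim(f) <- c(d[1] * d[2] * d[4], d[3])
  z <- crossprod(f, p$W)
  z <- sweep(z, 2, p$b, "+")
  list(out = z, cache = list(f = f, d = d))
}

fc_backward <- function(dz, p, cache) {
  d <- cache$d
  df <- p$W %*% t(dz)
  dW <- cache$f %*% dz
  db <- colSums(dz)
  dim(df) <- c(d[1], d[2], d[4], d[3])
  dx <- aperm(df, c(1, 2, 4, 3))
  list(dx = dx, dW = dW, db = db)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

cnn_forward <- function(model, x, training = FALSE, drop_mask = NULL) {
  p <- model$params
  d <- dim(x)
  a <- array(x, c(d[1], d[2], d[3], 1))
  caches <- list()
  for (i in 1:3) {
    cv <- paste0("conv", i)
    bn <- paste0("bn", i)
    z <- .conv_forward(a, p[[cv]]$W, p[[cv]]$b)
    caches[[cv]] <- a
    br <- .bnrelu_forward(z, p[[bn]]$gamma, p[[bn]]$beta,
                          p[[bn]]$run_mean, p[[bn]]$run_var, training)
    if (training) {
      p[[bn]]$run_mean <- br$run_mean
      p[[bn]]$run_var <- br$run_var
      caches[[bn]] <- list(xhat = br$xhat, istd = br$istd,
                           mask = br$mask)
    }
    pl <- .pool_forward(br$out)
    caches[[paste0("pool", i)]] <- list(which = pl$which,
                                        hw = dim(br$out)[1:2])
    a <- pl$out
  }
  if (model$cfg$dropout_position == "before_fc" && training &&
      !is.null(drop_mask)) {
    a <- a * drop_mask
  }
  fcres <- fc_forward(a, p$fc)
  caches$fc <- fcres$cache
  z <- fcres$out
  if (model$cfg$dropout_position == "after_fc" && training &&
      !is.null(drop_mask)) {
    z <- z * drop_mask
  }
  probs <- softmax_rows(z)
  list(probs = probs, logits = z, caches = caches, params = p)
}

# Gradient of mean cross-entropy wrt all parameters. `y` is 1/2 class index.
cnn_backward <- function(model, fw, y, drop_mask = NULL) {
  p <- fw$params
  n <- nrow(fw$probs)
  dz <- fw$probs
  dz[cbind(seq_len(n), y)] <- dz[cbind(seq_len(n), y)] - 1
  dz <- dz / n
  if (model$cfg$dropout_position == "after_fc" && !is.null(drop_mask))
    dz <- dz * drop_mask
  g <- list()
  fcb <- fc_backward(dz, p$fc, fw$caches$fc)
  g$fc <- list(W = fcb$dW, b = fcb$db)
  da <- fcb$dx
  if (model$cfg$dropout_position == "before_fc" && !is.null(drop_mask))
    da <- da * drop_mask
  for (i in 3:1) {
    pl <- fw$caches[[paste0("pool", i)]]
    da <- .pool_backward(da, pl$which, pl$hw[1], pl$hw[2])
    bc <- fw$caches[[paste0("bn", i)]]
    bnb <- .bnrelu_backward(da, bc$xhat, p[[paste0("bn", i)]]$gamma,
                            bc$istd, bc$mask)
    g[[paste0("bn", i)]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    cvb <- .conv_backward(fw$caches[[paste0("conv", i)]],
                          p[[paste0("conv", i)]]$W, bnb$dx)
    g[[paste0("conv", i)]] <- list(W = cvb$dW, b = cvb$db)
    da <- cvb$dX
  }
  g
}

#' Train the patch classifier with SGDM
#'
#' Mini-batch stochastic gradient descent with momentum and cross-entropy
#' loss on a split [patch_dataset()]. The learning rate decays
#' geometrically per epoch from `lr_initial` to `lr_final` over the planned
#' run; training stops when either the epoch or the iteration cap is
#' reached. Dropout is active only during training; batch-norm statistics
#' are frozen at their running values for validation. Runs are reproducible
#' for a fixed `tc$seed` on a single worker.
#'
#' @param model an `infarct_cnn` from [build_cnn()].
#' @param ds a [patch_dataset()] with a train/validation split and both
#'   classes present in the training set.
#' @param tc a [train_config()].
#' @param verbose print per-epoch progress every `verbose` epochs (0 = off).
#' @return The trained model; `model$history` holds the per-epoch log
#'   (epoch, iteration, learning rate, mean loss, validation accuracy in
#'   percent).
#' @export
train_cnn <- function(model, ds, tc = train_config(), verbose = 0) {
  if (!inherits(model, "infarct_cnn")) stop("`model` must be an infarct_cnn",
                                            call. = FALSE)
  if (is.null(ds$split)) stop("dataset has no train/validation split",
                              call. = FALSE)
  tr_idx <- which(ds$split == "train")
  va_idx <- which(ds$split == "validation")
  tr <- patch_array(ds$patches[tr_idx])
  y <- match(tr$labels, model$classes)
  if (length(unique(y)) < 2)
    stop("training set must contain both classes", call. = FALSE)
  has_val <- length(va_idx) > 0
  if (has_val) {
    va <- patch_array(ds$patches[va_idx])
    yv <- match(va$labels, model$classes)
  }
  n <- length(y)
  steps_per_epoch <- ceiling(n / tc$batch_size)
  planned_epochs <- min(tc$max_epochs,
                        ceiling(tc$max_iterations / steps_per_epoch))
  lr_for_epoch <- function(e) {
    if (planned_epochs <= 1) return(tc$lr_initial)
    tc$lr_initial * (tc$lr_final / tc$lr_initial)^((e - 1) /
                                                   (planned_epochs - 1))
  }
  vel <- rapply(model$params, function(x) x * 0, how = "replace")
  history <- vector("list", planned_epochs)
  iter <- 0L
  drop_rate <- model$cfg$dropout
  with_seed(tc$seed, {
    for (epoch in seq_len(planned_epochs)) {
      lr <- lr_for_epoch(epoch)
      ord <- sample(n)
      losses <- numeric(0)
      for (s in seq_len(steps_per_epoch)) {
        if (iter >= tc$max_iterations) break
        take <- ord[((s - 1) * tc$batch_size + 1):min(s * tc$batch_size, n)]
        xb <- tr$x[, , take, drop = FALSE]
        yb <- y[take]
        nb <- length(take)
        dmask <- NULL
        if (drop_rate > 0) {
          sz <- if (model$cfg$dropout_position == "after_fc")
            nb * model$cfg$n_class
          else nb * (model$cfg$input_size / 8)^2 * model$cfg$conv_filters[3]
          dmask <- (stats::runif(sz) >= drop_rate) / (1 - drop_rate)
          if (model$cfg$dropout_position == "after_fc")
            dim(dmask) <- c(nb, model$cfg$n_class)
          else
            dim(dmask) <- c(model$cfg$input_size / 8,
                            model$cfg$input_size / 8, nb,
                            model$cfg$conv_filters[3])
        }
        fw <- cnn_forward(model, xb, training = TRUE, drop_mask = dmask)
        model$params <- fw$params # batch-norm running stats
        pr <- fw$probs[cbind(seq_len(nb), yb)]
        losses <- c(losses, -mean(log(pmax(pr, 1e-12))))
        g <- cnn_backward(model, fw, yb, drop_mask = dmask)
        for (ly in names(g)) {
          for (par in names(g[[ly]])) {
            grad <- g[[ly]][[par]]
            if (par == "W") # L2 decay on weights only
              grad <- grad + tc$weight_decay * model$params[[ly]][[par]]
            vel[[ly]][[par]] <- tc$momentum * vel[[ly]][[par]] - lr * grad
            model$params[[ly]][[par]] <- model$params[[ly]][[par]] +
              vel[[ly]][[par]]
          }
        }
        iter <- iter + 1L
      }
      val_acc <- NA_real_
      if (has_val) {
        pv <- cnn_forward(model, va$x, training = FALSE)$probs
        val_acc <- 100 * mean(max.col(pv, ties.method = "first") == yv)
      }
      history[[epoch]] <- data.frame(epoch = epoch, iteration = iter,
                                     lr = lr, loss = mean(losses),
                                     val_accuracy = val_acc)
      if (verbose > 0 && epoch %% verbose == 0)
        message(sprintf("epoch %d/%d iter %d lr %.3g loss %.4f val %.1f",
                        epoch, planned_epochs, iter, lr, mean(losses),
                        val_acc))
      if (iter >= tc$max_iterations) break
    }
  })
  model$history <- do.call(rbind, history[!vapply(history, is.null, TRUE)])
  model$trained <- TRUE
  model
}

#' Classify patches with a trained model
#'
#' Deterministic inference: dropout is disabled and batch-norm uses its
#' running statistics.
#'
#' @param model a trained `infarct_cnn`.
#' @param patches list of [ct_patch()] objects (or a [patch_dataset()]).
#' @param batch_size inference batch size.
#' @return A data frame with one row per patch: predicted `label`,
#'   `probability` of the predicted class, and `prob_infarcted`.
#' @export
predict_patches <- function(model, patches, batch_size = 2000) {
  if (!isTRUE(model$trained))
    stop("model has not been trained", call. = FALSE)
  if (inherits(patches, "patch_dataset")) patches <- patches$patches
  n <- length(patches)
  pa <- patch_array(patches)
  probs <- matrix(0, n, model$cfg$n_class)
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1, n)
    probs[take, ] <- cnn_forward(model, pa$x[, , take, drop = FALSE],
                                 training = FALSE)$probs
  }
  cls <- max.col(probs, ties.method = "first")
  data.frame(
    label = model$classes[cls],
    probability = probs[cbind(seq_len(n), cls)],
    prob_infarcted = probs[, 1],
    stringsAsFactors = FALSE
  )
}

#' @describeIn predict_patches `predict` method for `infarct_cnn`.
#' @param object an `infarct_cnn`.
#' @param ... passed on.
#' @export
predict.infarct_cnn <- function(object, patches, ...) {
  predict_patches(object, patches, ...)
}

#' Save / load a trained classifier
#'
#' Checkpoint with configuration, weights, running statistics and seed.
#'
#' @param model an `infarct_cnn`.
#' @param path checkpoint file path.
#' @return `path` (save) or the model (load).
#' @export
save_cnn <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) readRDS(path)

#' Confusion matrix of patch-level classification
#'
#' Counts (or percentages) of true positive, false negative, false positive
#' and true negative decisions. Positive means infarcted.
#'
#' @param TP,FN,FP,TN nonnegative counts or percentages.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  v <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(v < 0) || all(v == 0))
    stop("confusion matrix entries must be nonnegative and not all zero",
         call. = FALSE)
  structure(as.list(v), class = "confusion_matrix")
}

#' Tabulate predictions against ground truth
#'
#' @param truth,predicted character vectors of `"infarcted"` /
#'   `"non_infarcted"` labels.
#' @return A [confusion_matrix()].
#' @export
confusion_from_labels <- function(truth, predicted) {
  confusion_matrix(
    TP = sum(truth == "infarcted" & predicted == "infarcted"),
    FN = sum(truth == "infarcted" & predicted == "non_infarcted"),
    FP = sum(truth == "non_infarcted" & predicted == "infarcted"),
    TN = sum(truth == "non_infarcted" & predicted == "non_infarcted")
  )
}

#' Accuracy, sensitivity and specificity in percent
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`; all
#' scale-invariant, so counts and percentages give identical results.
#' Values are returned in percent, unrounded; the print method shows one
#' decimal.
#'
#' @param cm a [confusion_matrix()].
#' @return An object of class `detection_metrics`: list with `accuracy`,
#'   `sensitivity`, `specificity` (percent).
#' @export
compute_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix"))
    stop("`cm` must be a confusion_matrix", call. = FALSE)
  tot <- cm$TP + cm$TN + cm$FP + cm$FN
  structure(
    list(
      accuracy = 100 * (cm$TP + cm$TN) / tot,
      sensitivity = if (cm$TP + cm$FN > 0) 100 * cm$TP / (cm$TP + cm$FN)
                    else NA_real_,
      specificity = if (cm$TN + cm$FP > 0) 100 * cm$TN / (cm$TN + cm$FP)
                    else NA_real_
    ),
    class = "detection_metrics"
  )
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              round_half_up(x$accuracy, 1), round_half_up(x$sensitivity, 1),
              round_half_up(x$specificity, 1)))
  invisible(x)
}
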