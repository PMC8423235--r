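#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1-y) log(1-p))` over all pixels, with probabilities
#' clamped to `[eps, 1-eps]`.  Uniform 0.5 predictions give `log(2)`; perfect
#' predictions approach 0.
#'
#' @param prob numeric array of probabilities.
#' @param target binary array of the same shape.
#' @param eps clamp (default 1e-7).
#' @return scalar loss.
#' @export
bce_loss <- function(prob, target, eps = 1e-7) {
  if (!identical(dim(prob), dim(target)) || length(prob) != length(target))
    stop("probability and target shapes differ", call. = FALSE)
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

bce_grad <- function(prob, target, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  g <- (p - target) / (p * (1 - p)) / length(p)
  g[prob <= eps | prob >= 1 - eps] <- 0   # loss is flat where p was clamped
  g
}

# -- Adam --------------------------------------------------------------------

adam_state <- function(layers) {
  lapply(layers, function(l)
    lapply(l$pnames, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0)))
}

adam_step <- function(layers, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (j in seq_along(l$pnames)) {
      p <- l$pnames[j]
      g <- l[[paste0("g_", p)]]
      s <- st[[i]][[j]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      mh <- s$m / (1 - beta1^t)
      vh <- s$v / (1 - beta2^t)
      l[[p]] <- l[[p]] - lr * mh / (sqrt(vh) + eps)
      st[[i]][[j]] <- s
    }
  }
  st
}

pairs_to_batch <- function(pairs) {
  d <- dim(pairs[[1]]$image)
  x <- array(0, dim = c(d[1], d[2], 3, length(pairs)))
  y <- array(0, dim = c(d[1], d[2], 1, length(pairs)))
  for (i in seq_along(pairs)) {
    x[, , , i] <- pairs[[i]]$image
    y[, , 1, i] <- pairs[[i]]$mask
  }
  list(x = x, y = y)
}

#' Train a vessel-segmentation network
#'
#' From-scratch, seeded optimization of a network on a set of image/mask
#' pairs with the Adam optimizer and binary cross-entropy loss (the
#' training protocol of the model family: learning rate 0.008, batch size 2;
#' 100/50/80 epochs for DRIVE/CHASE-DB1/STARE).  A fraction of the training
#' images can be held out for per-epoch validation; the returned object keeps
#' both the final weights and the state of the best-validation-F1 epoch.
#'
#' @param data list of [image_pair()]s whose dims are divisible by
#'   `2^depth`.
#' @param variant,depth,base_channels,block model configuration passed to
#'   [hdc_model()] (ignored when `model` is given).
#' @param model optionally, an already-built [hdc_model()] to train.
#' @param epochs number of passes over the training images.
#' @param learning_rate Adam learning rate (default 0.008).
#' @param batch_size images per optimization step (default 2).
#' @param validation_fraction fraction of images held out for validation
#'   (default 0; the protocol default for real datasets is 0.1).
#' @param seed integer seed controlling initialization, shuffling, DropBlock
#'   masks and the validation split.
#' @param verbose print per-epoch progress.
#' @return an object of class `hdc_fit` with elements `model`, `history`
#'   (per-epoch data frame), `best_state`, `config`.
#' @export
hdc_fit <- function(data, variant = "hdcnet", depth = 3L, base_channels = 32L,
                    block = block_config(), model = NULL, epochs = 10L,
                    learning_rate = 0.008, batch_size = 2L,
                    validation_fraction = 0, seed = 1L, verbose = FALSE) {
  stopifnot(length(data) >= 1, epochs >= 1, learning_rate > 0, batch_size >= 1)
  set.seed(seed)
  if (is.null(model))
    model <- hdc_model(variant, depth, base_channels, block)
  n_val <- floor(validation_fraction * length(data))
  val_idx <- if (n_val > 0) sample(seq_along(data), n_val) else integer()
  train_set <- if (n_val > 0) data[-val_idx] else data
  val_set <- data[val_idx]
  if (!length(train_set)) stop("no training images left after split", call. = FALSE)
  layers <- model_layers(model)
  st <- adam_state(layers)
  t_step <- 0L
  hist <- vector("list", epochs)
  best_f1 <- -Inf; best_state <- NULL; best_epoch <- NA_integer_
  for (ep in seq_len(epochs)) {
    ord <- sample(seq_along(train_set))
    ep_loss <- 0; n_batch <- 0
    tp <- fp <- tn <- fn <- 0
    for (b0 in seq(1, length(ord), by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1, length(ord))]
      batch <- pairs_to_batch(train_set[idx])
      prob <- model_forward(model, batch$x, training = TRUE)
      loss <- bce_loss(prob, batch$y)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
      cache <- attr(prob, "cache")
      for (l in layers) layer_zero_grad(l)
      model_backward(model, bce_grad(prob, batch$y), cache)
      t_step <- t_step + 1L
      st <- adam_step(layers, st, learning_rate, t_step)
      ep_loss <- ep_loss + loss; n_batch <- n_batch + 1
      pred <- prob > 0.5
      tp <- tp + sum(pred & batch$y == 1); fp <- fp + sum(pred & batch$y == 0)
      tn <- tn + sum(!pred & batch$y == 0); fn <- fn + sum(!pred & batch$y == 1)
    }
    tr_counts <- structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
                           class = "confusion_counts")
    tr <- segmentation_scores(tr_counts)
    va <- if (length(val_set)) eval_pairs_metrics(model, val_set) else
      list(loss = NA_real_, acc = NA_real_, f1 = NA_real_)
    hist[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / n_batch,
                             train_acc = tr$acc, train_f1 = tr$f1,
                             val_loss = va$loss, val_acc = va$acc,
                             val_f1 = va$f1)
    score <- if (length(val_set)) va$f1 else tr$f1
    if (!is.na(score) && score > best_f1) {
      best_f1 <- score; best_state <- model_state(model); best_epoch <- ep
    }
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train F1 %.4f  val F1 %s",
                      ep, ep_loss / n_batch, tr$f1,
                      ifelse(is.na(va$f1), "-", sprintf("%.4f", va$f1))))
  }
  final_train <- eval_pairs_metrics(model, train_set)
  structure(list(model = model, history = do.call(rbind, hist),
                 final_train = final_train,
                 best_state = best_state, best_epoch = best_epoch,
                 config = list(variant = model$variant, depth = model$depth,
                               base_channels = model$base_channels,
                               epochs = epochs, learning_rate = learning_rate,
                               batch_size = batch_size,
                               validation_fraction = validation_fraction,
                               seed = seed)),
            class = "hdc_fit")
}

eval_pairs_metrics <- function(model, pairs) {
  probs <- list(); gts <- list(); loss <- 0
  for (i in seq_along(pairs)) {
    pm <- predict(model, pairs[[i]])
    probs[[i]] <- pm; gts[[i]] <- pairs[[i]]$mask
    loss <- loss + bce_loss(pm, pairs[[i]]$mask)
  }
  cc <- NULL
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(probs)) {
    c1 <- confusion_counts(probs[[i]], gts[[i]])
    tp <- tp + c1$tp; fp <- fp + c1$fp; tn <- tn + c1$tn; fn <- fn + c1$fn
  }
  sc <- segmentation_scores(structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
                                      class = "confusion_counts"))
  list(loss = loss / length(pairs), acc = sc$acc, f1 = sc$f1)
}

#' Evaluate a model on a test set at native resolution
#'
#' For each test pair: pad to the target size, predict, crop the probability
#' map back to native resolution with [restore_original()], then pool
#' confusion counts and pixels over the whole set ([pool_metrics()]).
#'
#' @param model an [hdc_model()] or [hdc_fit()].
#' @param pairs list of [image_pair()]s at native resolution.
#' @param target integer `(height, width)` padded size, divisible by
#'   `2^depth`.
#' @param threshold classification threshold (default 0.5).
#' @return a `metric_report`.
#' @export
evaluate_model <- function(model, pairs, target, threshold = 0.5) {
  if (inherits(model, "hdc_fit")) model <- model$model
  if (!length(pairs)) stop("empty test partition", call. = FALSE)
  probs <- list(); gts <- list()
  for (i in seq_along(pairs)) {
    pp <- pad_to_target(pairs[[i]], target)
    pm <- predict(model, pp)
    probs[[i]] <- restore_original(pm, pp)
    gts[[i]] <- pairs[[i]]$mask
  }
  pool_metrics(probs, gts, threshold)
}

#' Cross-dataset generalization protocol
#'
#' Trains on one dataset's training pairs and evaluates on another dataset's
#' pairs at that dataset's own padded resolution — the cross-training measure
#' of generalization (train on DRIVE, test on STARE, and vice versa).
#'
#' @param train_pairs training [image_pair()]s (already at a trainable size).
#' @param test_pairs test pairs at native resolution.
#' @param test_target padded `(height, width)` for the test dataset.
#' @param ... passed to [hdc_fit()].
#' @return list with the fit and the test `metric_report`.
#' @export
cross_train <- function(train_pairs, test_pairs, test_target, ...) {
  fit <- hdc_fit(train_pairs, ...)
  report <- evaluate_model(fit$model, test_pairs, test_target)
  list(fit = fit, report = report)
}

#' Save / load a model checkpoint
#'
#' Checkpoints carry the serialized weights and buffers, the model
#' configuration, the training seed and epoch, and a format version, so a
#' run can be recreated and predictions reproduced bit-for-bit.
#'
#' @param model an [hdc_model()] or [hdc_fit()].
#' @param path file path.
#' @param seed,epoch optional provenance fields.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a rebuilt `hdc_model`.
#' @export
save_checkpoint <- function(model, path, seed = NA_integer_,
                            epoch = NA_integer_) {
  fit <- NULL
  if (inherits(model, "hdc_fit")) { fit <- model; model <- model$model }
  obj <- list(format = "hdcnet-checkpoint", version = 1L,
              variant = model$variant, depth = model$depth,
              base_channels = model$base_channels, block = model$block,
              in_channels = model$in_channels, out_channels = model$out_channels,
              state = model_state(model),
              seed = if (!is.null(fit)) fit$config$seed else seed,
              epoch = if (!is.null(fit)) nrow(fit$history) else epoch)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hdcnet-checkpoint"))
    stop("not a model checkpoint: ", path, call. = FALSE)
  m <- hdc_model(obj$variant, obj$depth, obj$base_channels, obj$block,
                 obj$in_channels, obj$out_channels)
  model_load_state(m, obj$state)
  m
}

# -- hdc_fit methods ---------------------------------------------------------

#' @export
print.hdc_fit <- function(x, ...) {
  cfg <- x$config
  cat("Fitted vessel segmentation network (", cfg$variant, ")\n", sep = "")
  cat("  epochs: ", cfg$epochs, ", lr: ", cfg$learning_rate, ", batch: ",
      cfg$batch_size, ", seed: ", cfg$seed, "\n", sep = "")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train loss %.4f, train F1 %.4f\n",
              last$train_loss, last$train_f1))
  if (!is.na(last$val_f1))
    cat(sprintf("  best validation F1 %.4f (epoch %d)\n",
                max(x$history$val_f1, na.rm = TRUE), x$best_epoch))
  invisible(x)
}

#' @export
summary.hdc_fit <- function(object, ...) {
  print(object)
  cat("  parameters: ", format(count_parameters(object$model),
                               big.mark = ","), "\n", sep = "")
  cat("  history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object$history)
}

#' Plot training curves
#'
#' Training (and, when present, validation) loss and F1 per epoch.
#'
#' @param x an [hdc_fit()].
#' @param ... passed to [plot()].
#' @export
plot.hdc_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "BCE loss",
       main = "loss", ...)
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  plot(h$epoch, h$train_f1, type = "l", xlab = "epoch", ylab = "F1",
       ylim = c(0, 1), main = "F1", ...)
  if (!all(is.na(h$val_f1)))
    graphics::lines(h$epoch, h$val_f1, lty = 2)
  invisible(x)
}

#' @export
predict.hdc_fit <- function(object, newdata, ...) predict(object$model, newdata, ...)

#' @export
coef.hdc_fit <- function(object, ...) coef(object$model, ...)
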