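test_that("binary cross-entropy has its analytic values", {
  y <- array(rbinom(25, 1, 0.5), dim = c(5, 5))
  expect_lt(bce_loss(y, y), 1e-5)                     # perfect fit limit
  expect_equal(bce_loss(array(0.5, dim(y)), y), log(2), tolerance = 1e-12)
  p <- c(0.9, 0.2, 0.6, 0.4, 0.99)
  t5 <- c(1, 0, 1, 0, 1)
  hand <- -mean(t5 * log(p) + (1 - t5) * log(1 - p))
  expect_equal(bce_loss(array(p, c(5, 1)), array(t5, c(5, 1))), hand,
               tolerance = 1e-12)
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("the BCE gradient matches finite differences away from the clamp", {
  set.seed(1)
  p <- array(runif(10, 0.05, 0.95), c(10, 1))
  y <- array(rbinom(10, 1, 0.5), c(10, 1))
  g <- hdcnet:::bce_grad(p, y)
  eps <- 1e-7
  for (i in c(1, 5, 10)) {
    pp <- p; pp[i] <- p[i] + eps
    pm <- p; pm[i] <- p[i] - eps
    expect_equal(g[i], (bce_loss(pp, y) - bce_loss(pm, y)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("fitting runs, records history, and is seed-reproducible", {
  pairs <- make_test_pairs(2, size = 32, seed = 20)
  f1 <- hdc_fit(pairs, variant = "sd_unet", depth = 2, base_channels = 4,
                epochs = 1, batch_size = 2, seed = 9)
  expect_s3_class(f1, "hdc_fit")
  expect_identical(nrow(f1$history), 1L)
  f2 <- hdc_fit(pairs, variant = "sd_unet", depth = 2, base_channels = 4,
                epochs = 1, batch_size = 2, seed = 9)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
})

test_that("a validation split is held out and tracked", {
  pairs <- make_test_pairs(4, size = 32, seed = 30)
  f <- hdc_fit(pairs, variant = "sd_unet", depth = 2, base_channels = 4,
               epochs = 2, batch_size = 2, validation_fraction = 0.25,
               seed = 2)
  expect_false(any(is.na(f$history$val_loss)))
  expect_false(is.na(f$best_epoch))
})

test_that("checkpoints round-trip to bit-identical predictions", {
  set.seed(4)
  pairs <- make_test_pairs(1, size = 32, seed = 40)
  m <- hdc_model("hdcnet", depth = 2, base_channels = 4)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path, seed = 4L, epoch = 0L)
  m2 <- load_checkpoint(path)
  expect_identical(predict(m, pairs[[1]]), predict(m2, pairs[[1]]))
  unlink(path)
})

test_that("evaluation pads, predicts, restores and pools; empty sets error", {
  set.seed(5)
  m <- hdc_model("sd_unet", depth = 2, base_channels = 4)
  pairs <- lapply(1:2, function(i) {
    set.seed(50 + i)
    image_pair(array(runif(30 * 27 * 3), dim = c(30, 27, 3)),
               random_mask(30, 27), paste0("odd", i))
  })
  rep <- evaluate_model(m, pairs, target = c(32L, 32L))
  expect_s3_class(rep, "metric_report")
  expect_identical(rep$counts$tp + rep$counts$fp + rep$counts$tn +
                     rep$counts$fn, 2L * 30L * 27L)
  expect_error(evaluate_model(m, list(), c(32L, 32L)), "empty")
})

test_that("cross-training on identical sets equals plain evaluation", {
  pairs <- make_test_pairs(2, size = 32, seed = 60)
  ct <- cross_train(pairs, pairs, test_target = c(32L, 32L),
                    variant = "sd_unet", depth = 2, base_channels = 4,
                    epochs = 1, seed = 3)
  direct <- evaluate_model(ct$fit$model, pairs, c(32L, 32L))
  expect_equal(ct$report$acc, direct$acc, tolerance = 1e-12)
  expect_equal(ct$report$auc, direct$auc, tolerance = 1e-12)
  expect_false(any(is.na(unlist(ct$report[c("se", "sp", "acc", "auc")]))))
})

test_that("training aborts with a clear error when the loss turns non-finite", {
  pairs <- make_test_pairs(1, size = 32, seed = 70)
  pairs[[1]]$image[1, 1, 1] <- NaN
  expect_error(
    hdc_fit(pairs, variant = "sd_unet", depth = 2, base_channels = 4,
            epochs = 2, batch_size = 1, seed = 1),
    "diverged", ignore.case = TRUE)
})
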