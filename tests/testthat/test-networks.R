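test_that("the full network maps an RGB image to an in-(0,1) probability map", {
  set.seed(1)
  m <- hdc_model("hdcnet", depth = 2, base_channels = 8)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  p <- predict(m, img)
  expect_equal(dim(p), c(64, 64))
  expect_true(all(p > 0) && all(p < 1))
})

test_that("variant gating adds and removes the right sub-modules", {
  set.seed(1)
  kinds <- function(m) vapply(hdcnet:::model_layers(m), function(l) l$kind, "")
  u <- hdc_model("unet", depth = 2, base_channels = 8)
  s <- hdc_model("sd_unet", depth = 2, base_channels = 8)
  h <- hdc_model("hdcnet", depth = 2, base_channels = 8)
  expect_false(any(vapply(u$enc[[1]]$sub, function(l) l$kind, "") == "dropblock"))
  expect_true(any(vapply(s$enc[[1]]$sub, function(l) l$kind, "") == "dropblock"))
  expect_false(any(kinds(u) == "rdeca"))
  expect_true(any(kinds(h) == "rdeca"))
  expect_length(u$enc_hdc, 0)
  expect_length(h$enc_hdc, 2)
})

test_that("no-residual ablation changes wiring but not the parameter count", {
  set.seed(1)
  a <- hdc_model("hdcnet", depth = 2, base_channels = 8)
  set.seed(1)
  b <- hdc_model("hdcnet_no_rc", depth = 2, base_channels = 8)
  expect_identical(count_parameters(a), count_parameters(b))
  expect_true(a$skips[[1]]$use_residual)
  expect_false(b$skips[[1]]$use_residual)
})

test_that("parameter count grows along the variant lattice", {
  set.seed(1)
  n_sd <- count_parameters(hdc_model("sd_unet"))
  n_rd <- count_parameters(hdc_model("sd_unet_rdeca"))
  n_hd <- count_parameters(hdc_model("hdcnet"))
  expect_lt(n_sd, n_rd)
  expect_lte(n_rd, n_hd)
})

test_that("a single 3x3 conv with bias from 1 to 1 channel has 10 parameters", {
  set.seed(1)
  expect_identical(hdcnet:::layer_n_params(hdcnet:::new_conv(1, 1, 3)), 10)
})

test_that("parameter count is invariant to input size", {
  set.seed(1)
  m <- hdc_model("hdcnet", depth = 2, base_channels = 8)
  n0 <- count_parameters(m)
  invisible(predict(m, array(runif(32 * 32 * 3), dim = c(32, 32, 3))))
  invisible(predict(m, array(runif(64 * 64 * 3), dim = c(64, 64, 3))))
  expect_identical(count_parameters(m), n0)
})

test_that("prediction is deterministic in eval mode and errors on bad dims", {
  set.seed(2)
  m <- hdc_model("hdcnet", depth = 2, base_channels = 8)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  expect_identical(predict(m, img), predict(m, img))
  bad <- array(runif(30 * 30 * 3), dim = c(30, 30, 3))
  expect_error(predict(m, bad), "divisible.*pad", ignore.case = TRUE)
})

test_that("a constant image maps to an interior map that is shift-2^depth periodic", {
  # stride-2 transposed convolutions tile the output with period 2, so the
  # translation invariance of an all-conv net on constant input holds modulo
  # that period in the interior (away from border effects)
  set.seed(3)
  m <- hdc_model("hdcnet", depth = 1, base_channels = 4)
  img <- array(0.37, dim = c(96, 96, 3))
  p <- predict(m, img)
  expect_equal(p[45:52, 45:52], p[47:54, 47:54], tolerance = 1e-10)
  expect_equal(p[45:52, 45:52], p[45:52, 47:54], tolerance = 1e-10)
})

test_that("one optimizer epoch at a small learning rate reduces the loss", {
  pairs <- make_test_pairs(1, size = 32, seed = 5)
  fit1 <- hdc_fit(pairs, variant = "hdcnet", depth = 2, base_channels = 4,
                  epochs = 2, learning_rate = 1e-4, batch_size = 1, seed = 3,
                  block = block_config(dropblock_drop_rate = 0))
  # with DropBlock off and batch == full set, epoch losses are exact
  expect_lte(fit1$history$train_loss[2],
             fit1$history$train_loss[1] + 1e-6)
})

test_that("the calibration grid search ranks the shipped default best for U-Net", {
  set.seed(1)
  grid <- calibrate_config(depths = 3, bases = c(16L, 32L))
  top <- grid[grid$variant == "unet" & grid$diff == 0, ]
  expect_identical(nrow(top), 1L)
  expect_identical(top$depth, 3)
  expect_identical(top$base_channels, 32L)
})
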