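test_that("conv_unit preserves spatial dims and maps channels", {
  set.seed(1)
  u <- conv_unit(3, 16)
  x <- array(runif(32 * 32 * 3), dim = c(32, 32, 3, 1))
  y <- block_forward(u, x)
  expect_equal(dim(y), c(32, 32, 16, 1))
  expect_error(block_forward(u, matrix(1, 4, 4)), "4-D")
})

test_that("conv_unit with zero weights and identity BN gives all zeros in eval mode", {
  set.seed(1)
  u <- conv_unit(2, 4, block_config(dropblock_drop_rate = 0))
  for (l in hdcnet:::collect_layers(u)) {
    if (l$kind == "conv") { l$w[] <- 0; l$b[] <- 0 }
  }
  x <- array(runif(8 * 8 * 2), dim = c(8, 8, 2, 1))
  expect_true(all(block_forward(u, x, training = FALSE) == 0))
})

test_that("conv_unit matches a hand-composed conv -> BN -> ReLU pipeline", {
  set.seed(7)
  u <- conv_unit(2, 3, block_config(dropblock_drop_rate = 0))
  x <- array(rnorm(8 * 8 * 2), dim = c(8, 8, 2, 1))
  y <- block_forward(u, x, training = FALSE)
  convs <- Filter(function(l) l$kind == "conv", hdcnet:::collect_layers(u))
  ref <- x
  for (cv in convs) {
    ref <- naive_conv2d(ref, cv$w, cv$b, pad = 1, dil = 1)
    # eval-mode BN at initialization scales by 1/sqrt(1 + eps)
    ref <- pmax(ref / sqrt(1 + 1e-5), 0)
  }
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("dropblock is the identity in eval mode and at zero rate", {
  x <- array(runif(16 * 16 * 2 * 2), dim = c(16, 16, 2, 2))
  expect_identical(dropblock(x, training = FALSE), x)
  expect_identical(dropblock(x, drop_rate = 0, training = TRUE), x)
  expect_error(dropblock(x, block_size = 17, training = TRUE), "block_size")
})

test_that("dropblock empirical drop fraction converges to the nominal rate", {
  x <- array(1, dim = c(64, 64, 1, 1))
  set.seed(42)
  fractions <- replicate(1000, {
    y <- dropblock(x, block_size = 7, drop_rate = 0.15, training = TRUE)
    mean(y == 0)
  })
  expect_lt(abs(mean(fractions) - 0.15), 0.02)
})

test_that("dropblock rescales survivors to preserve the expected sum", {
  x <- array(1, dim = c(32, 32, 1, 1))
  set.seed(9)
  y <- dropblock(x, block_size = 5, drop_rate = 0.2, training = TRUE)
  expect_equal(sum(y), sum(x), tolerance = 1e-9)
})

test_that("spatial attention with zero weights is 0.5 everywhere", {
  set.seed(1)
  s <- sam_block(7)
  s$conv$w[] <- 0; s$conv$b[] <- 0
  x <- array(rnorm(16 * 16 * 8 * 2), dim = c(16, 16, 8, 2))
  a <- block_forward(s, x)
  expect_equal(dim(a), c(16, 16, 1, 2))
  expect_true(all(a == 0.5))
})

test_that("spatial attention output lies strictly in (0,1) and rejects even kernels", {
  set.seed(2)
  s <- sam_block(7)
  x <- array(rnorm(16 * 16 * 8 * 2), dim = c(16, 16, 8, 2))
  a <- block_forward(s, x)
  expect_true(all(a > 0) && all(a < 1))
  expect_error(sam_block(4), "odd")
})

test_that("spatial attention matches hand computation of pooled maps, conv, sigmoid", {
  set.seed(3)
  s <- sam_block(7)
  x <- array(rnorm(3 * 3 * 2 * 1), dim = c(3, 3, 2, 1))
  a <- block_forward(s, x)
  stacked <- array(0, dim = c(3, 3, 2, 1))
  stacked[, , 1, 1] <- pmax(x[, , 1, 1], x[, , 2, 1])
  stacked[, , 2, 1] <- (x[, , 1, 1] + x[, , 2, 1]) / 2
  ref <- 1 / (1 + exp(-naive_conv2d(stacked, s$conv$w, s$conv$b, pad = 3)))
  expect_equal(a, ref, tolerance = 1e-12)
})

test_that("hdc block preserves shape and rejects odd channel counts", {
  set.seed(4)
  b <- hdc_block(16)
  x <- array(rnorm(32 * 32 * 16), dim = c(32, 32, 16, 1))
  expect_equal(dim(block_forward(b, x)), c(32, 32, 16, 1))
  expect_error(hdc_block(5), "even")
})

test_that("hdc block with all weights zero is the identity (residual path)", {
  set.seed(5)
  b <- hdc_block(8)
  for (l in hdcnet:::collect_layers(b)) { l$w[] <- 0; l$b[] <- 0 }
  x <- array(rnorm(16 * 16 * 8 * 2), dim = c(16, 16, 8, 2))
  expect_equal(block_forward(b, x), x, tolerance = 1e-14)
})

test_that("dilation-2 branch response to an impulse sits at offsets -2, 0, +2", {
  set.seed(6)
  b <- hdc_block(8)
  x0 <- array(0, dim = c(16, 16, 4, 1))     # the dilation-2 half in isolation
  x1 <- x0; x1[8, 9, 2, 1] <- 1
  y0 <- b$conv2$fw(x0)
  y1 <- b$conv2$fw(x1)
  dlt <- abs(y1 - y0)
  hit <- which(apply(dlt, c(1, 2), max) > 0, arr.ind = TRUE)
  expect_true(all(hit[, 1] %in% (8 + c(-2, 0, 2))))
  expect_true(all(hit[, 2] %in% (9 + c(-2, 0, 2))))
})

test_that("channel attention preserves shape and scales by 1.5 at zero weights", {
  set.seed(7)
  r <- rdeca_block(8)
  x <- array(rnorm(16 * 16 * 8 * 1), dim = c(16, 16, 8, 1))
  expect_equal(dim(block_forward(r, x)), dim(x))
  r$reduce$w[] <- 0; r$reduce$b[] <- 0; r$w1d[] <- 0; r$b1d <- 0
  expect_equal(block_forward(r, x), 1.5 * x, tolerance = 1e-14)
})

test_that("channel attention matches a hand-computed 4-channel example", {
  set.seed(8)
  r <- rdeca_block(4)
  # channel-constant input: max and average descriptors must coincide
  x <- array(rep(c(1, -2, 0.5, 3), each = 4 * 4), dim = c(4, 4, 4, 1))
  y <- block_forward(r, x)
  desc <- c(1, -2, 0.5, 3)                       # max == mean per channel
  u <- as.numeric(matrix(r$reduce$w[1, 1, , ], ncol = 4, byrow = FALSE) |>
                    crossprod(c(desc, desc))) + r$reduce$b
  u <- pmax(u, 0)
  z <- numeric(4)
  for (c in 1:4) for (j in 1:3) {
    src <- c + j - 2
    if (src >= 1 && src <= 4) z[c] <- z[c] + r$w1d[j] * u[src]
  }
  wts <- 1 / (1 + exp(-(z + r$b1d)))
  ref <- x
  for (c in 1:4) ref[, , c, 1] <- x[, , c, 1] * (1 + wts[c])
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("blocks preserve batch and spatial dims over randomized shapes", {
  set.seed(9)
  for (rep in 1:5) {
    H <- sample(seq(8, 24, 2), 1); W <- sample(seq(8, 24, 2), 1)
    C <- sample(c(4, 8, 12), 1); N <- sample(2, 1)
    x <- array(rnorm(H * W * C * N), dim = c(H, W, C, N))
    expect_equal(dim(block_forward(hdc_block(C), x)), c(H, W, C, N))
    expect_equal(dim(block_forward(rdeca_block(C), x)), c(H, W, C, N))
    expect_equal(dim(block_forward(sam_block(7), x)), c(H, W, 1, N))
  }
})

test_that("blocks are deterministic given fixed weights and inputs", {
  set.seed(10)
  b <- hdc_block(8)
  x <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8, 1))
  expect_identical(block_forward(b, x), block_forward(b, x))
  set.seed(11); m1 <- dropblock(x, 5, 0.3, TRUE, rng_seed = 99)
  set.seed(12); m2 <- dropblock(x, 5, 0.3, TRUE, rng_seed = 99)
  expect_identical(m1, m2)
})
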