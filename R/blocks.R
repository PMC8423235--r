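#' Block hyperparameters
#'
#' Bundles the hyperparameters shared by the network building blocks: the
#' DropBlock regularizer (block size and drop rate), the dilation rates of the
#' two hierarchical-dilation branches, the spatial-attention kernel, the
#' 1-D cross-channel kernel of the channel-attention module, and whether the
#' channel-attention module keeps its additive residual connection.
#'
#' @param dropblock_block_size odd integer, side of the square patches zeroed
#'   by DropBlock (default 7).
#' @param dropblock_drop_rate expected fraction of activations dropped during
#'   training, in `[0, 1]` (default 0.15).
#' @param hdc_dilations integer pair of dilation rates for the two branches of
#'   the hierarchical dilation block (default `c(1, 2)`).
#' @param sam_kernel odd integer, kernel size of the spatial-attention
#'   convolution (default 7).
#' @param rdeca_1d_kernel odd integer, kernel of the 1-D cross-channel
#'   convolution in the channel-attention module (default 3).
#' @param use_residual logical; keep the residual connection of the
#'   channel-attention module (default `TRUE`; the `*_no_rc` model variants
#'   set it to `FALSE`).
#' @return an object of class `block_config`.
#' @export
block_config <- function(dropblock_block_size = 7L, dropblock_drop_rate = 0.15,
                         hdc_dilations = c(1L, 2L), sam_kernel = 7L,
                         rdeca_1d_kernel = 3L, use_residual = TRUE) {
  stopifnot(dropblock_block_size >= 1, dropblock_block_size %% 2 == 1,
            dropblock_drop_rate >= 0, dropblock_drop_rate <= 1,
            length(hdc_dilations) == 2, all(hdc_dilations >= 1),
            sam_kernel %% 2 == 1, rdeca_1d_kernel %% 2 == 1)
  structure(list(dropblock_block_size = as.integer(dropblock_block_size),
                 dropblock_drop_rate = dropblock_drop_rate,
                 hdc_dilations = as.integer(hdc_dilations),
                 sam_kernel = as.integer(sam_kernel),
                 rdeca_1d_kernel = as.integer(rdeca_1d_kernel),
                 use_residual = isTRUE(use_residual)),
            class = "block_config")
}

#' Structured DropBlock regularization
#'
#' Zeroes contiguous `block_size` x `block_size` patches of each channel of a
#' feature map during training and rescales the survivors so the expected
#' activation sum is preserved.  Seed centers are drawn Bernoulli(gamma) on
#' the valid region, with
#' `gamma = drop_rate * H * W / (block_size^2 * (H-block_size+1) * (W-block_size+1))`.
#' In evaluation mode, or when `drop_rate` is zero, the input is returned
#' unchanged.
#'
#' @param x 4-D feature map `(H, W, C, N)`.
#' @param block_size odd integer, no larger than either spatial dim.
#' @param drop_rate expected dropped fraction in `[0, 1]`.
#' @param training logical; masks are only drawn in training mode.
#' @param rng_seed optional integer seed for a reproducible mask.
#' @return feature map of the same shape.
#' @export
dropblock <- function(x, block_size = 7L, drop_rate = 0.15, training = TRUE,
                      rng_seed = NULL) {
  x <- as_feature_map(x)
  m <- dropblock_mask(dim(x), block_size, drop_rate, training, rng_seed)
  if (is.null(m)) x else x * m
}

# Returns NULL for the identity case, otherwise the rescaled keep-mask
# (already multiplied by total/kept per channel-sample slice).
dropblock_mask <- function(d, block_size, drop_rate, training, rng_seed = NULL) {
  if (!training || drop_rate <= 0) return(NULL)
  H <- d[1]; W <- d[2]
  if (block_size > min(H, W))
    stop("dropblock block_size (", block_size, ") exceeds feature map dims (",
         H, "x", W, ")", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  half <- (block_size - 1L) %/% 2L
  nvh <- H - block_size + 1L; nvw <- W - block_size + 1L
  gamma <- drop_rate * H * W / (block_size^2 * nvh * nvw)
  mask <- array(1, dim = d)
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    seeds <- which(matrix(runif(nvh * nvw) < gamma, nvh, nvw), arr.ind = TRUE)
    m <- matrix(1, H, W)
    if (nrow(seeds)) {
      for (s in seq_len(nrow(seeds))) {
        ch <- seeds[s, 1] + half; cw <- seeds[s, 2] + half
        m[(ch - half):(ch + half), (cw - half):(cw + half)] <- 0
      }
    }
    kept <- sum(m)
    mask[, , c, n] <- if (kept > 0) m * (length(m) / kept) else m
  }
  mask
}

new_dropblock <- function(block_size, drop_rate) {
  l <- new_layer()
  l$kind <- "dropblock"
  l$block_size <- block_size; l$drop_rate <- drop_rate
  l$fw <- function(x, training = FALSE) {
    l$mask <- dropblock_mask(dim(x), l$block_size, l$drop_rate, training)
    if (is.null(l$mask)) x else x * l$mask
  }
  l$bw <- function(gy) if (is.null(l$mask)) gy else gy * l$mask
  l
}

#' Basic convolution unit
#'
#' Two successive (3x3 convolution, DropBlock, batch normalization, ReLU)
#' stages, the elementary encoder/decoder unit of the network.  Spatial
#' dimensions are preserved (padding 1); the output has `out_channels`
#' channels.  With `use_dropblock = FALSE` (the plain U-Net variant) the
#' DropBlock stages are omitted.
#'
#' @param in_channels,out_channels positive integers.
#' @param cfg a [block_config()].
#' @param use_dropblock logical.
#' @return a block object; apply it with [block_forward()].
#' @export
conv_unit <- function(in_channels, out_channels, cfg = block_config(),
                      use_dropblock = TRUE) {
  stopifnot(out_channels >= 1)
  seqs <- list()
  cin <- in_channels
  for (i in 1:2) {
    seqs[[length(seqs) + 1]] <- new_conv(cin, out_channels, 3L)
    if (use_dropblock)
      seqs[[length(seqs) + 1]] <- new_dropblock(cfg$dropblock_block_size,
                                                cfg$dropblock_drop_rate)
    seqs[[length(seqs) + 1]] <- new_bn(out_channels)
    seqs[[length(seqs) + 1]] <- new_relu()
    cin <- out_channels
  }
  b <- new_layer()
  b$kind <- "conv_unit"; b$sub <- seqs
  b$fw <- function(x, training = FALSE) {
    for (s in b$sub) x <- s$fw(x, training)
    x
  }
  b$bw <- function(gy) {
    for (s in rev(b$sub)) gy <- s$bw(gy)
    gy
  }
  b
}

#' Spatial attention block
#'
#' Channel-wise max and mean maps of the input are stacked into a two-channel
#' map, convolved with a single `kernel` x `kernel` filter, and passed through
#' a sigmoid, giving a per-pixel attention map in `(0, 1)` of shape
#' `(H, W, 1, N)`.
#'
#' @param kernel odd integer kernel size (default 7).
#' @return a block object; apply it with [block_forward()].
#' @export
sam_block <- function(kernel = 7L) {
  if (kernel %% 2 == 0) stop("spatial attention kernel must be odd", call. = FALSE)
  b <- new_layer()
  b$kind <- "sam"
  b$conv <- new_conv(2L, 1L, as.integer(kernel))
  b$sig <- new_sigmoid()
  b$sub <- list(b$conv)
  b$fw <- function(x, training = FALSE) {
    d <- dim(x); C <- d[3]
    mx <- x[, , 1, , drop = FALSE]
    am <- array(1L, dim = c(d[1], d[2], 1, d[4]))
    if (C > 1) for (c in 2:C) {
      xc <- x[, , c, , drop = FALSE]
      upd <- xc > mx
      mx[upd] <- xc[upd]
      am[upd] <- c
    }
    mean_map <- array(0, dim = c(d[1], d[2], 1, d[4]))
    for (c in seq_len(C)) mean_map <- mean_map + x[, , c, , drop = FALSE]
    mean_map <- mean_map / C
    b$argmax <- am; b$C <- C; b$din <- d
    stacked <- array(0, dim = c(d[1], d[2], 2, d[4]))
    stacked[, , 1, ] <- mx
    stacked[, , 2, ] <- mean_map
    b$sig$fw(b$conv$fw(stacked, training), training)
  }
  b$bw <- function(gy) {
    gs <- b$conv$bw(b$sig$bw(gy))
    d <- b$din
    gx <- array(0, dim = d)
    gmax <- gs[, , 1, , drop = FALSE]
    gmean <- gs[, , 2, , drop = FALSE] / b$C
    for (c in seq_len(d[3])) {
      gc <- gmean + gmax * (b$argmax == c)
      gx[, , c, ] <- gc
    }
    gx
  }
  b
}

#' Hierarchical dilation convolution block
#'
#' Splits the input evenly along the channel axis, applies a 3x3 convolution
#' with dilation 1 to one half and dilation 2 to the other (each preserving
#' its channel count and the spatial dims), concatenates the results, refines
#' them with a spatial-attention map, and adds the block input back through a
#' residual connection: `F + SAM(Y3) * Y3`.  Channel count and resolution are
#' unchanged.
#'
#' @param channels even positive integer, channels of the input feature map.
#' @param cfg a [block_config()].
#' @return a block object; apply it with [block_forward()].
#' @export
hdc_block <- function(channels, cfg = block_config()) {
  if (channels %% 2 != 0)
    stop("hierarchical dilation block needs an even channel count (got ",
         channels, ")", call. = FALSE)
  half <- channels %/% 2L
  b <- new_layer()
  b$kind <- "hdc"
  b$half <- half
  b$conv1 <- new_conv(half, half, 3L, dil = cfg$hdc_dilations[1])
  b$conv2 <- new_conv(half, half, 3L, dil = cfg$hdc_dilations[2])
  b$sam <- sam_block(cfg$sam_kernel)
  b$sub <- list(b$conv1, b$conv2, b$sam)
  b$fw <- function(x, training = FALSE) {
    d <- dim(x)
    if (d[3] != 2 * b$half)
      stop("hdc block built for ", 2 * b$half, " channels, got ", d[3],
           call. = FALSE)
    y1 <- b$conv1$fw(x[, , seq_len(b$half), , drop = FALSE], training)
    y2 <- b$conv2$fw(x[, , b$half + seq_len(b$half), , drop = FALSE], training)
    y3 <- array(0, dim = d)
    y3[, , seq_len(b$half), ] <- y1
    y3[, , b$half + seq_len(b$half), ] <- y2
    a <- b$sam$fw(y3, training)
    b$y3 <- y3; b$a <- a
    x + y3 * bc_attention(a, d)
  }
  b$bw <- function(gy) {
    d <- dim(gy)
    abc <- bc_attention(b$a, d)
    ga <- apply(gy * b$y3, c(1, 2, 4), sum)          # collapse channels
    ga <- array(ga, dim = c(d[1], d[2], 1, d[4]))
    gy3 <- gy * abc + b$sam$bw(ga)
    gx <- gy                                          # residual path
    gx[, , seq_len(b$half), ] <- gx[, , seq_len(b$half), , drop = FALSE] +
      b$conv1$bw(gy3[, , seq_len(b$half), , drop = FALSE])
    idx2 <- b$half + seq_len(b$half)
    gx[, , idx2, ] <- gx[, , idx2, , drop = FALSE] +
      b$conv2$bw(gy3[, , idx2, , drop = FALSE])
    gx
  }
  b
}

# broadcast an (H, W, 1, N) attention map over channels
bc_attention <- function(a, d) {
  out <- array(0, dim = d)
  for (c in seq_len(d[3])) out[, , c, ] <- a
  out
}

#' Residual dual efficient channel attention block
#'
#' Global max-pool and global average-pool channel descriptors are
#' concatenated (2C), reduced back to C by a 1x1 convolution with ReLU, mixed
#' across neighbouring channels by a 1-D convolution (kernel
#' `cfg$rdeca_1d_kernel`, zero padded), and squashed by a sigmoid into channel
#' weights `w` in `(0,1)^C`.  The output is `x + x * w` (or `x * w` when the
#' residual connection is disabled via `cfg$use_residual = FALSE`).
#'
#' @param channels positive integer, at least `cfg$rdeca_1d_kernel`.
#' @param cfg a [block_config()].
#' @return a block object; apply it with [block_forward()].
#' @export
rdeca_block <- function(channels, cfg = block_config()) {
  if (channels < cfg$rdeca_1d_kernel)
    stop("rdeca needs at least ", cfg$rdeca_1d_kernel, " channels", call. = FALSE)
  b <- new_layer(c("w1d", "b1d"))
  b$kind <- "rdeca"
  b$C <- as.integer(channels)
  b$use_residual <- cfg$use_residual
  b$reduce <- new_conv(2L * channels, channels, 1L, pad = 0L)
  k <- cfg$rdeca_1d_kernel
  b$k <- as.integer(k)
  b$w1d <- rnorm(k, 0, sqrt(2 / k)); b$g_w1d <- numeric(k)
  b$b1d <- 0; b$g_b1d <- 0
  b$sub <- list(b$reduce)
  b$fw <- function(x, training = FALSE) {
    d <- dim(x); C <- d[3]; N <- d[4]
    dmax <- matrix(0, C, N); amax <- matrix(0L, C, N)
    davg <- matrix(0, C, N)
    HW <- d[1] * d[2]
    for (n in seq_len(N)) for (c in seq_len(C)) {
      sl <- x[, , c, n]
      i <- which.max(sl)
      dmax[c, n] <- sl[i]; amax[c, n] <- i
      davg[c, n] <- mean(sl)
    }
    desc <- array(0, dim = c(1, 1, 2 * C, N))
    desc[1, 1, seq_len(C), ] <- dmax
    desc[1, 1, C + seq_len(C), ] <- davg
    u <- b$reduce$fw(desc, training)
    b$relu_mask <- u > 0
    u <- u * b$relu_mask
    um <- matrix(u, C, N)
    half <- (b$k - 1L) %/% 2L
    z <- matrix(0, C, N)
    for (j in seq_len(b$k)) {
      off <- j - 1L - half
      src <- seq_len(C) + off
      ok <- src >= 1 & src <= C
      z[ok, ] <- z[ok, , drop = FALSE] + b$w1d[j] * um[src[ok], , drop = FALSE]
    }
    z <- z + b$b1d
    wts <- 1 / (1 + exp(-z))
    b$x <- x; b$um <- um; b$wts <- wts; b$amax <- amax; b$HW <- HW
    wb <- bc_channel_batch(wts, d)
    if (b$use_residual) x + x * wb else x * wb
  }
  b$bw <- function(gy) {
    d <- dim(gy); C <- d[3]; N <- d[4]
    wb <- bc_channel_batch(b$wts, d)
    gx <- if (b$use_residual) gy + gy * wb else gy * wb
    # grad into channel weights: sum over spatial of gy * x
    gw_cn <- matrix(0, C, N)
    for (n in seq_len(N)) for (c in seq_len(C))
      gw_cn[c, n] <- sum(gy[, , c, n] * b$x[, , c, n])
    gz <- gw_cn * b$wts * (1 - b$wts)
    b$g_b1d <- b$g_b1d + sum(gz)
    half <- (b$k - 1L) %/% 2L
    gum <- matrix(0, C, N)
    for (j in seq_len(b$k)) {
      off <- j - 1L - half
      src <- seq_len(C) + off
      ok <- src >= 1 & src <= C
      b$g_w1d[j] <- b$g_w1d[j] +
        sum(gz[ok, , drop = FALSE] * b$um[src[ok], , drop = FALSE])
      gum[src[ok], ] <- gum[src[ok], , drop = FALSE] + b$w1d[j] * gz[ok, , drop = FALSE]
    }
    gu <- array(gum, dim = c(1, 1, C, N)) * b$relu_mask
    gdesc <- b$reduce$bw(gu)
    for (n in seq_len(N)) for (c in seq_len(C)) {
      gx_sl <- gx[, , c, n]
      gx_sl[b$amax[c, n]] <- gx_sl[b$amax[c, n]] + gdesc[1, 1, c, n]
      gx[, , c, n] <- gx_sl + gdesc[1, 1, C + c, n] / b$HW
    }
    gx
  }
  b
}

#' Apply a network block to a feature map
#'
#' Runs one of the building blocks ([conv_unit()], [sam_block()],
#' [hdc_block()], [rdeca_block()]) forward on a `(H, W, C, N)` array.
#'
#' @param block a block object.
#' @param x 4-D numeric array `(H, W, C, N)`.
#' @param training logical; enables DropBlock masking and batch statistics.
#' @return the transformed feature map.
#' @export
block_forward <- function(block, x, training = FALSE) {
  block$fw(as_feature_map(x), training)
}

# collect every parameterized layer inside a block, recursively
collect_layers <- function(b) {
  out <- list()
  if (length(b$pnames)) out[[length(out) + 1]] <- b
  for (s in b$sub) out <- c(out, collect_layers(s))
  out
}
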