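#' @useDynLib hdcnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif
NULL

# -- tensor helpers ----------------------------------------------------------
# Feature maps are numeric arrays with dim = (H, W, C, N): spatial rows,
# spatial columns, channels, batch.  All layers below are small mutable
# environments exposing fw(x, training) / bw(gy), with parameters and their
# accumulated gradients stored as fields so an optimizer can update in place.

as_feature_map <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 4L)
    stop("feature map must be a 4-D array (H, W, C, N)", call. = FALSE)
  if (!all(is.finite(x))) stop("feature map contains non-finite values", call. = FALSE)
  x
}

# broadcast a per-channel vector over (H, W, C, N)
bc_channel <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), d[4]), dim = d)
}

# broadcast a (C, N) matrix over (H, W, C, N)
bc_channel_batch <- function(m, d) {
  array(rep(as.numeric(m), each = d[1] * d[2]), dim = d)
}

new_layer <- function(pnames = character()) {
  e <- new.env(parent = emptyenv())
  e$pnames <- pnames
  e
}

layer_zero_grad <- function(l) {
  for (p in l$pnames) l[[paste0("g_", p)]] <- l[[paste0("g_", p)]] * 0
  invisible(l)
}

layer_n_params <- function(l) sum(vapply(l$pnames, function(p) length(l[[p]]), 0))

# -- 2-D convolution ---------------------------------------------------------

new_conv <- function(cin, cout, k = 3L, pad = (k - 1L) %/% 2L, dil = 1L,
                     bias = TRUE) {
  l <- new_layer(if (bias) c("w", "b") else "w")
  l$kind <- "conv"
  # padding for a dilated k-kernel that preserves spatial dims is dil*(k-1)/2;
  # callers can override (e.g. pad = 0 for 1x1 convs)
  l$pad <- if (missing(pad)) as.integer(dil * (k - 1L) / 2L) else as.integer(pad)
  l$dil <- as.integer(dil)
  sd <- sqrt(2 / (k * k * cin))
  l$w <- array(rnorm(k * k * cin * cout, 0, sd), dim = c(k, k, cin, cout))
  l$g_w <- l$w * 0
  if (bias) { l$b <- numeric(cout); l$g_b <- numeric(cout) }
  l$fw <- function(x, training = FALSE) {
    l$x <- x
    conv2d_fw(x, dim(x), l$w, dim(l$w),
              if (is.null(l$b)) numeric(0) else l$b, l$pad, l$dil)
  }
  l$bw <- function(gy) {
    g <- conv2d_bw(l$x, dim(l$x), l$w, dim(l$w), gy, l$pad, l$dil,
                   !is.null(l$b))
    l$g_w <- l$g_w + g$gw
    if (!is.null(l$b)) l$g_b <- l$g_b + g$gb
    g$gx
  }
  l
}

# -- transposed convolution, kernel 3, stride 2 (exact x2 upsampling) --------

new_tconv <- function(cin, cout, bias = TRUE) {
  l <- new_layer(if (bias) c("w", "b") else "w")
  l$kind <- "tconv"
  sd <- sqrt(2 / (9 * cin))
  l$w <- array(rnorm(9 * cin * cout, 0, sd), dim = c(3L, 3L, cin, cout))
  l$g_w <- l$w * 0
  if (bias) { l$b <- numeric(cout); l$g_b <- numeric(cout) }
  l$fw <- function(x, training = FALSE) {
    l$x <- x
    tconv2d_fw(x, dim(x), l$w, dim(l$w),
               if (is.null(l$b)) numeric(0) else l$b)
  }
  l$bw <- function(gy) {
    g <- tconv2d_bw(l$x, dim(l$x), l$w, dim(l$w), gy, !is.null(l$b))
    l$g_w <- l$g_w + g$gw
    if (!is.null(l$b)) l$g_b <- l$g_b + g$gb
    g$gx
  }
  l
}

# -- batch normalization -----------------------------------------------------

new_bn <- function(C, eps = 1e-5, momentum = 0.1) {
  l <- new_layer(c("gamma", "beta"))
  l$kind <- "bn"; l$eps <- eps; l$momentum <- momentum
  l$gamma <- rep(1, C); l$beta <- numeric(C)
  l$g_gamma <- numeric(C); l$g_beta <- numeric(C)
  l$run_mean <- numeric(C); l$run_var <- rep(1, C)
  l$fw <- function(x, training = FALSE) {
    d <- dim(x)
    if (training) {
      xr <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
      m <- colMeans(xr)
      v <- colMeans(xr * xr) - m * m
      v <- pmax(v, 0)
      l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * m
      l$run_var  <- (1 - l$momentum) * l$run_var  + l$momentum * v
    } else {
      m <- l$run_mean; v <- l$run_var
    }
    inv <- 1 / sqrt(v + l$eps)
    xhat <- (x - bc_channel(m, d)) * bc_channel(inv, d)
    l$xhat <- xhat; l$inv <- inv; l$training <- training
    xhat * bc_channel(l$gamma, d) + bc_channel(l$beta, d)
  }
  l$bw <- function(gy) {
    d <- dim(gy)
    M <- d[1] * d[2] * d[4]
    per_ch_sum <- function(a) colSums(matrix(aperm(a, c(1, 2, 4, 3)), ncol = d[3]))
    l$g_gamma <- l$g_gamma + per_ch_sum(gy * l$xhat)
    l$g_beta  <- l$g_beta + per_ch_sum(gy)
    gxhat <- gy * bc_channel(l$gamma, d)
    if (isTRUE(l$training)) {
      s1 <- per_ch_sum(gxhat)
      s2 <- per_ch_sum(gxhat * l$xhat)
      (gxhat - bc_channel(s1 / M, d) - l$xhat * bc_channel(s2 / M, d)) *
        bc_channel(l$inv, d)
    } else {
      gxhat * bc_channel(l$inv, d)
    }
  }
  l
}

# -- activations -------------------------------------------------------------

new_relu <- function() {
  l <- new_layer()
  l$kind <- "relu"
  l$fw <- function(x, training = FALSE) { l$mask <- x > 0; x * l$mask }
  l$bw <- function(gy) gy * l$mask
  l
}

new_sigmoid <- function() {
  l <- new_layer()
  l$kind <- "sigmoid"
  l$fw <- function(x, training = FALSE) { l$y <- 1 / (1 + exp(-x)); l$y }
  l$bw <- function(gy) gy * l$y * (1 - l$y)
  l
}
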