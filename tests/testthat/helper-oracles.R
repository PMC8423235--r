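# Independent oracles and small fixtures used across the suite.
# Everything here is deliberately naive (direct loops / exhaustive
# enumeration) so it cannot share a bug with the implementation.

# plain-loop 2-D convolution, stride 1, zero padding, optional dilation
naive_conv2d <- function(x, w, b = NULL, pad = 1L, dil = 1L) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; O <- dim(w)[4]
  Ho <- H + 2 * pad - dil * (k - 1); Wo <- W + 2 * pad - dil * (k - 1)
  y <- array(0, dim = c(Ho, Wo, O, N))
  for (n in 1:N) for (o in 1:O) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- if (is.null(b)) 0 else b[o]
    for (c in 1:C) for (i in 1:k) for (j in 1:k) {
      hi <- ho - pad + dil * (i - 1); wi <- wo - pad + dil * (j - 1)
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, c, n] * w[i, j, c, o]
    }
    y[ho, wo, o, n] <- acc
  }
  y
}

# exhaustive per-pixel confusion tally
naive_confusion <- function(prob, gt, thr = 0.5) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(prob)) {
    pred <- prob[i] > thr
    if (pred && gt[i] == 1) tp <- tp + 1
    else if (pred && gt[i] == 0) fp <- fp + 1
    else if (!pred && gt[i] == 0) tn <- tn + 1
    else fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# O(n^2) pairwise Mann-Whitney AUC with ties counted one half
naive_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# small batch of phantom pairs for training smoke tests
make_test_pairs <- function(n = 2, size = 32, seed = 1) {
  lapply(seq_len(n), function(i)
    generate_phantom(phantom_spec(size = c(size, size), seed = seed + i)))
}

random_mask <- function(H, W, p = 0.2) matrix(as.numeric(rbinom(H * W, 1, p)), H, W)
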