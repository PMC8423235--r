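#' Synthetic fundus phantom specification
#'
#' Parameters of the seeded phantom generator: RGB images with curvilinear
#' branching dark structures (1-8 px wide) on a textured, unevenly
#' illuminated background, paired with exact binary masks.  Phantoms let
#' every stage of the pipeline run with no dataset download; they emulate
#' the multi-scale, thin-vessel geometry of fundus photographs, not their
#' photometric statistics.
#'
#' @param size integer `(height, width)` (default `c(64, 64)`).
#' @param n_trees number of vessel trees (default 2).
#' @param branch_prob per-step probability that a walker spawns a branch
#'   (default 0.03).
#' @param width_range `(min, max)` vessel width in pixels; tapers from root
#'   (max) to tip (min) (default `c(1, 3)`, the thin-vessel regime).
#' @param tortuosity standard deviation of the per-step heading change in
#'   radians (default 0.2).
#' @param background list with `base` (RGB triple), `illumination`
#'   (radial-gradient amplitude) and `noise_sd` (Gaussian pixel noise).
#' @param fov_radius_fraction optional radius of a circular field of view
#'   (fraction of the half-diagonal) outside which the image is darkened;
#'   `NULL` for none.
#' @param seed integer; the same seed always reproduces the same phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(64L, 64L), n_trees = 2L, branch_prob = 0.03,
                         width_range = c(1, 3), tortuosity = 0.2,
                         background = list(base = c(0.82, 0.45, 0.25),
                                           illumination = 0.25,
                                           noise_sd = 0.02),
                         fov_radius_fraction = NULL, seed = 1L) {
  stopifnot(all(size >= 16), n_trees >= 0, branch_prob >= 0, branch_prob <= 1,
            width_range[1] >= 1, width_range[2] >= width_range[1],
            tortuosity >= 0)
  structure(list(size = as.integer(size), n_trees = as.integer(n_trees),
                 branch_prob = branch_prob, width_range = width_range,
                 tortuosity = tortuosity, background = background,
                 fov_radius_fraction = fov_radius_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# stamp a disc of diameter `width` at (r, c) into acc (max-combine);
# soft = anti-aliased edge for the drawn image, hard = binary for the mask
stamp_disc <- function(acc, r, c, width, soft) {
  H <- nrow(acc); W <- ncol(acc)
  rad <- width / 2
  lo_r <- max(1, floor(r - rad - 1)); hi_r <- min(H, ceiling(r + rad + 1))
  lo_c <- max(1, floor(c - rad - 1)); hi_c <- min(W, ceiling(c + rad + 1))
  if (lo_r > hi_r || lo_c > hi_c) return(acc)
  rr <- lo_r:hi_r; cc <- lo_c:hi_c
  d <- sqrt(outer((rr - r)^2, (cc - c)^2, `+`))
  v <- if (soft) pmin(pmax(rad + 0.5 - d, 0), 1) else (d <= rad) * 1
  acc[rr, cc] <- pmax(acc[rr, cc], v)
  acc
}

grow_tree <- function(H, W, spec) {
  # root on a random border, heading inward
  side <- sample(4, 1)
  pos <- switch(side,
                c(1, runif(1, 1, W)), c(H, runif(1, 1, W)),
                c(runif(1, 1, H), 1), c(runif(1, 1, H), W))
  heading <- atan2(H / 2 - pos[1], W / 2 - pos[2]) + rnorm(1, 0, 0.3)
  max_len <- round(1.2 * max(H, W))
  walkers <- list(list(pos = pos, heading = heading,
                       width = spec$width_range[2], age = 0))
  pts <- list()
  total_steps <- 0
  while (length(walkers) && total_steps < 20 * max_len) {
    wk <- walkers[[1]]; walkers <- walkers[-1]
    repeat {
      total_steps <- total_steps + 1
      wk$age <- wk$age + 1
      frac <- min(wk$age / max_len, 1)
      width <- wk$width - (wk$width - spec$width_range[1]) * frac
      pts[[length(pts) + 1]] <- c(wk$pos, width)
      wk$heading <- wk$heading + rnorm(1, 0, spec$tortuosity)
      wk$pos <- wk$pos + c(sin(wk$heading), cos(wk$heading))
      if (wk$pos[1] < 1 || wk$pos[1] > H || wk$pos[2] < 1 || wk$pos[2] > W)
        break
      if (wk$age >= max_len || width <= spec$width_range[1] * 0.75) break
      if (runif(1) < spec$branch_prob && width > spec$width_range[1]) {
        walkers[[length(walkers) + 1]] <-
          list(pos = wk$pos,
               heading = wk$heading + sample(c(-1, 1), 1) * runif(1, 0.4, 1.1),
               width = max(width * 0.7, spec$width_range[1]),
               age = wk$age)
      }
      if (total_steps >= 20 * max_len) break
    }
  }
  pts
}

#' Generate one phantom image pair
#'
#' Vessel skeletons are grown as random branching walks (curvature bounded
#' by `tortuosity`, Galton-Watson-style splits with width reduction), the
#' width tapering from root to tip.  The binary mask is the hard-dilated
#' skeleton; the image draws the same vessels anti-aliased and darker than a
#' background with a radial illumination gradient, then adds Gaussian noise
#' (the noise never alters the mask).
#'
#' @param spec a [phantom_spec()].
#' @return an [image_pair()].
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  H <- spec$size[1]; W <- spec$size[2]
  hard <- matrix(0, H, W)
  soft <- matrix(0, H, W)
  if (spec$n_trees > 0) for (k in seq_len(spec$n_trees)) {
    pts <- grow_tree(H, W, spec)
    for (p in pts) {
      hard <- stamp_disc(hard, p[1], p[2], p[3], soft = FALSE)
      soft <- stamp_disc(soft, p[1], p[2], p[3], soft = TRUE)
    }
  }
  # background: base color with radial illumination falloff plus mild texture
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ctr_r <- H * runif(1, 0.35, 0.65); ctr_c <- W * runif(1, 0.35, 0.65)
  dist <- sqrt((rr - ctr_r)^2 + (cc - ctr_c)^2) / (sqrt(H^2 + W^2) / 2)
  illum <- 1 - spec$background$illumination * dist^2
  img <- array(0, dim = c(H, W, 3))
  depth_contrast <- c(0.35, 0.55, 0.45)       # vessels darkest in green
  for (ch in 1:3) {
    plane <- spec$background$base[ch] * illum
    plane <- plane * (1 - depth_contrast[ch] * soft)
    plane <- plane + rnorm(H * W, 0, spec$background$noise_sd)
    img[, , ch] <- plane
  }
  if (!is.null(spec$fov_radius_fraction)) {
    fov <- dist <= spec$fov_radius_fraction
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (0.05 + 0.95 * fov)
  }
  img <- pmin(pmax(img, 0), 1)
  image_pair(img, hard, sprintf("phantom_seed%d", spec$seed))
}

#' Write a phantom dataset to disk
#'
#' Generates `n_images` seeded phantoms (seeds `spec$seed + 0:(n-1)`), writes
#' image/mask PNG pairs plus a plain-text partition file (first half train,
#' second half test), and returns a [dataset_spec()] that [load_dataset()]
#' accepts.
#'
#' @param spec a [phantom_spec()].
#' @param n_images number of pairs (>= 1).
#' @param out_dir output directory.
#' @return a `dataset_spec` for the written dataset.
#' @export
make_phantom_dataset <- function(spec, n_images, out_dir) {
  stopifnot(n_images >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  stems <- character(n_images)
  for (i in seq_len(n_images)) {
    si <- spec; si$seed <- spec$seed + i - 1L
    p <- generate_phantom(si)
    p$source_id <- sprintf("phantom_%03d", i)
    stems[i] <- write_pair_png(p, out_dir)
  }
  n_train <- ceiling(n_images / 2)
  part <- data.frame(stem = stems,
                     split = rep(c("train", "test"),
                                 c(n_train, n_images - n_train)))
  utils::write.table(part, file.path(out_dir, "partition.txt"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  dataset_spec("phantom", spec$size, spec$size, dir = out_dir,
               train_ids = stems[seq_len(n_train)],
               test_ids = if (n_train < n_images)
                 stems[(n_train + 1):n_images] else character())
}
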