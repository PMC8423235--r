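#' Paired fundus image and vessel mask
#'
#' Couples an RGB image with its pixel-aligned binary vessel mask and the
#' provenance metadata (original size, padding offsets) needed to restore
#' predictions to native resolution after evaluation.
#'
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @param mask `H x W` binary matrix (0/1).
#' @param source_id identifier string.
#' @param original_size integer pair `(height, width)`; defaults to the
#'   current size.
#' @param pad_offsets integer pair `(top, left)` recorded by
#'   [pad_to_target()].
#' @return object of class `image_pair`.
#' @export
image_pair <- function(image, mask, source_id = "pair",
                       original_size = dim(mask), pad_offsets = c(0L, 0L)) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be H x W x 3", call. = FALSE)
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image and mask are not spatially aligned", call. = FALSE)
  if (!all(mask %in% c(0, 1))) stop("mask must be strictly binary", call. = FALSE)
  structure(list(image = image, mask = mask, source_id = source_id,
                 original_size = as.integer(original_size[1:2]),
                 pad_offsets = as.integer(pad_offsets)),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat("image_pair '", x$source_id, "': ", dim(x$mask)[1], "x", dim(x$mask)[2],
      " (native ", x$original_size[1], "x", x$original_size[2], "), ",
      round(100 * mean(x$mask), 1), "% vessel pixels\n", sep = "")
  invisible(x)
}

#' Zero-pad an image pair to a target resolution
#'
#' Pads image and mask symmetrically with zeros to the target size (the extra
#' pixel of an odd remainder goes to the bottom/right), recording the
#' `(top, left)` offsets so [restore_original()] can crop predictions back
#' exactly.  The standard targets take DRIVE 584x565 to 592x592, CHASE-DB1
#' 960x999 to 1008x1008 and STARE 605x700 to 704x704.
#'
#' @param p an [image_pair()].
#' @param target integer pair `(height, width)`, at least the current size.
#' @return padded `image_pair` with offsets recorded.
#' @export
pad_to_target <- function(p, target) {
  stopifnot(inherits(p, "image_pair"))
  d <- dim(p$mask)
  if (any(target < d)) stop("target size is smaller than the image", call. = FALSE)
  top <- (target[1] - d[1]) %/% 2L
  left <- (target[2] - d[2]) %/% 2L
  img <- array(0, dim = c(target, 3L))
  img[top + seq_len(d[1]), left + seq_len(d[2]), ] <- p$image
  msk <- matrix(0, target[1], target[2])
  msk[top + seq_len(d[1]), left + seq_len(d[2])] <- p$mask
  image_pair(img, msk, p$source_id, original_size = p$original_size,
             pad_offsets = c(top, left))
}

#' Crop a prediction back to native resolution
#'
#' Inverts [pad_to_target()] using the recorded offsets, so evaluation runs
#' at the dataset's original resolution.  `restore_original(pad_to_target(p,
#' t)$mask, p_padded)` is bit-identical to the unpadded mask.
#'
#' @param prob_map matrix at the padded size (probability map or mask).
#' @param p the padded [image_pair()] carrying `original_size` and
#'   `pad_offsets`.
#' @return matrix of size `original_size`.
#' @export
restore_original <- function(prob_map, p) {
  stopifnot(inherits(p, "image_pair"))
  if (is.null(p$pad_offsets)) stop("pad offsets missing", call. = FALSE)
  if (!identical(dim(prob_map), dim(p$mask)))
    stop("map is not at the padded size", call. = FALSE)
  os <- p$original_size; off <- p$pad_offsets
  prob_map[off[1] + seq_len(os[1]), off[2] + seq_len(os[2]), drop = FALSE]
}

#' Four corner crops
#'
#' Crops a pair into four `crop x crop` tiles anchored at the four corners
#' (overlapping whenever `2*crop` exceeds a dimension); their union always
#' covers every pixel.  Used to split large training images (e.g. 1008x1008
#' CHASE-DB1 pairs into four 512x512 tiles).
#'
#' @param p an [image_pair()].
#' @param crop tile side in pixels, no larger than either dimension.
#' @return list of four `image_pair`s, each recording its own offsets.
#' @export
corner_crops <- function(p, crop) {
  stopifnot(inherits(p, "image_pair"))
  d <- dim(p$mask)
  if (crop > min(d)) stop("crop size exceeds image dims", call. = FALSE)
  anchors <- list(c(0L, 0L), c(0L, d[2] - crop), c(d[1] - crop, 0L),
                  c(d[1] - crop, d[2] - crop))
  lapply(seq_along(anchors), function(i) {
    a <- anchors[[i]]
    image_pair(p$image[a[1] + seq_len(crop), a[2] + seq_len(crop), , drop = FALSE],
               p$mask[a[1] + seq_len(crop), a[2] + seq_len(crop), drop = FALSE],
               paste0(p$source_id, "_crop", i),
               original_size = c(crop, crop), pad_offsets = a)
  })
}

# -- augmentation ------------------------------------------------------------

rotate_raster <- function(m, angle, bilinear = TRUE) {
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  # inverse map: rotate output coords by -angle about the center
  yr <- cos(th) * (g$r - cy) + sin(th) * (g$c - cx) + cy
  xr <- -sin(th) * (g$r - cy) + cos(th) * (g$c - cx) + cx
  out <- numeric(H * W)
  if (bilinear) {
    y0 <- floor(yr); x0 <- floor(xr)
    fy <- yr - y0; fx <- xr - x0
    val <- function(r, c) {
      ok <- r >= 1 & r <= H & c >= 1 & c <= W
      v <- numeric(length(r))
      v[ok] <- m[cbind(r[ok], c[ok])]
      v
    }
    out <- (1 - fy) * (1 - fx) * val(y0, x0) + (1 - fy) * fx * val(y0, x0 + 1) +
      fy * (1 - fx) * val(y0 + 1, x0) + fy * fx * val(y0 + 1, x0 + 1)
  } else {
    rn <- round(yr); cn <- round(xr)
    ok <- rn >= 1 & rn <= H & cn >= 1 & cn <= W
    out[ok] <- m[cbind(rn[ok], cn[ok])]
  }
  matrix(out, H, W)
}

apply_flip <- function(m, type) {
  switch(type,
         horizontal = m[, rev(seq_len(ncol(m))), drop = FALSE],
         vertical = m[rev(seq_len(nrow(m))), , drop = FALSE],
         diagonal = t(m))
}

#' Augment an image pair
#'
#' Applies the four training-time augmentations: random-angle rotation
#' (0-360 degrees; image bilinear, mask nearest-neighbour, zero fill),
#' additive Gaussian noise (image only, clipped to `[0, 1]`),
#' hue/contrast/brightness jitter (image only), and a flip (horizontal,
#' vertical or main-diagonal transpose, both image and mask; the diagonal
#' flip requires a square pair).  Identical seeds give identical output, and
#' geometric transforms are applied jointly to image and mask.
#'
#' @param p an [image_pair()].
#' @param ops character subset of `c("rotate", "noise", "jitter", "flip")`.
#' @param rng_seed integer seed.
#' @param noise_sd Gaussian noise standard deviation (default 0.02).
#' @param hue_delta,brightness_delta,contrast_delta jitter half-ranges
#'   (defaults 0.05, 0.2, 0.2).
#' @return augmented `image_pair`.
#' @export
augment_pair <- function(p, ops = c("rotate", "noise", "jitter", "flip"),
                         rng_seed = NULL, noise_sd = 0.02, hue_delta = 0.05,
                         brightness_delta = 0.2, contrast_delta = 0.2) {
  stopifnot(inherits(p, "image_pair"))
  ops <- match.arg(ops, c("rotate", "noise", "jitter", "flip"),
                   several.ok = TRUE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  img <- p$image; msk <- p$mask
  if ("rotate" %in% ops) {
    ang <- runif(1, 0, 360)
    for (ch in 1:3) img[, , ch] <- rotate_raster(img[, , ch], ang, TRUE)
    msk <- rotate_raster(msk, ang, FALSE)
  }
  if ("flip" %in% ops) {
    choices <- c("horizontal", "vertical",
                 if (nrow(msk) == ncol(msk)) "diagonal")
    type <- sample(choices, 1)
    for (ch in 1:3) img[, , ch] <- apply_flip(img[, , ch], type)
    msk <- apply_flip(msk, type)
  }
  if ("jitter" %in% ops) {
    hsv <- grDevices::rgb2hsv(rbind(as.numeric(img[, , 1]),
                                    as.numeric(img[, , 2]),
                                    as.numeric(img[, , 3])), maxColorValue = 1)
    hsv[1, ] <- (hsv[1, ] + runif(1, -hue_delta, hue_delta)) %% 1
    rgb <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])) / 255
    for (ch in 1:3) img[, , ch] <- matrix(rgb[ch, ], nrow(msk), ncol(msk))
    img <- img * (1 + runif(1, -contrast_delta, contrast_delta))
    img <- img + runif(1, -brightness_delta, brightness_delta)
  }
  if ("noise" %in% ops)
    img <- img + rnorm(length(img), 0, noise_sd)
  img <- pmin(pmax(img, 0), 1)
  msk <- round(msk)
  image_pair(img, msk, p$source_id, original_size = p$original_size,
             pad_offsets = p$pad_offsets)
}

# -- dataset I/O -------------------------------------------------------------

#' Dataset description
#'
#' Names a dataset directory layout: native and padded target resolutions,
#' an optional training-time crop size, and the train/test partition by file
#' stem.
#'
#' @param name dataset name.
#' @param native_size,target_size integer `(height, width)` pairs; the target
#'   must be at least the native size and divisible by `2^depth` of the model
#'   it feeds.
#' @param dir directory containing `images/` and `masks/` subdirectories.
#' @param train_ids,test_ids character vectors of file stems.
#' @param crop_size optional integer for [corner_crops()].
#' @return object of class `dataset_spec`.
#' @export
dataset_spec <- function(name, native_size, target_size, dir = NULL,
                         train_ids = character(), test_ids = character(),
                         crop_size = NULL) {
  stopifnot(all(target_size >= native_size))
  structure(list(name = name, native_size = as.integer(native_size),
                 target_size = as.integer(target_size), dir = dir,
                 train_ids = train_ids, test_ids = test_ids,
                 crop_size = crop_size),
            class = "dataset_spec")
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported raster format: .", ext,
                     " (png and tiff are supported)", call. = FALSE))
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

#' Load an image/mask dataset from disk
#'
#' Reads image and mask rasters (PNG or TIFF) from `images/` and `masks/`
#' under the dataset directory, matching them by filename stem.  Masks are
#' binarized at 127/255; grey masks trip a warning.  Pairs are returned in
#' lexical stem order.
#'
#' @param spec a [dataset_spec()] (its `dir` is used), or a directory path.
#' @param ids optional stems to load (default: all images present).
#' @return list of [image_pair()]s.
#' @export
load_dataset <- function(spec, ids = NULL) {
  root <- if (inherits(spec, "dataset_spec")) spec$dir else spec
  img_dir <- file.path(root, "images"); msk_dir <- file.path(root, "masks")
  if (!dir.exists(img_dir) || !dir.exists(msk_dir))
    stop("dataset directory must contain images/ and masks/", call. = FALSE)
  imgs <- sort(list.files(img_dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE))
  stems <- tools::file_path_sans_ext(imgs)
  if (!is.null(ids)) {
    missing_ids <- setdiff(ids, stems)
    if (length(missing_ids))
      stop("images missing for stems: ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    keep <- stems %in% ids
    imgs <- imgs[keep]; stems <- stems[keep]
  }
  msk_files <- list.files(msk_dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  msk_stems <- tools::file_path_sans_ext(msk_files)
  lapply(seq_along(imgs), function(i) {
    j <- match(stems[i], msk_stems)
    if (is.na(j))
      stop("no mask found for image stem '", stems[i], "'", call. = FALSE)
    img <- read_raster(file.path(img_dir, imgs[i]))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
    msk <- read_raster(file.path(msk_dir, msk_files[j]))
    if (length(dim(msk)) == 3) msk <- msk[, , 1]
    if (!all(msk %in% c(0, 1))) {
      if (any(msk > 0.1 & msk < 0.9))
        warning("mask '", stems[i], "' has intermediate grey values; ",
                "thresholding at 127/255")
      msk <- as.numeric(msk > 127 / 255)
    }
    image_pair(img, matrix(msk, dim(img)[1], dim(img)[2]), stems[i])
  })
}

#' Write an image pair to disk as PNG
#'
#' @param p an [image_pair()].
#' @param dir dataset directory (an `images/` and `masks/` pair of
#'   subdirectories is created).
#' @return the stem, invisibly.
#' @export
write_pair_png <- function(p, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(p$image, file.path(dir, "images", paste0(p$source_id, ".png")))
  png::writePNG(p$mask, file.path(dir, "masks", paste0(p$source_id, ".png")))
  invisible(p$source_id)
}
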