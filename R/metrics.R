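#' Pixel confusion counts at a threshold
#'
#' Thresholds a probability map (strictly greater than `threshold` counts as
#' vessel; ties go to background) and tallies true/false positives/negatives
#' against a binary ground-truth mask.
#'
#' @param prob numeric matrix of probabilities.
#' @param gt binary matrix (0/1) of the same shape.
#' @param threshold scalar in `(0, 1)`; default 0.5.
#' @param mask optional logical matrix restricting the evaluated domain (e.g.
#'   a field-of-view mask); default evaluates every pixel.
#' @return object of class `confusion_counts`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion_counts <- function(prob, gt, threshold = 0.5, mask = NULL) {
  if (!identical(dim(prob), dim(gt)))
    stop("probability map and ground truth have different shapes", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1)
  if (!all(gt %in% c(0, 1))) stop("ground truth must be binary", call. = FALSE)
  keep <- if (is.null(mask)) TRUE else as.logical(mask)
  p <- prob[keep]; g <- gt[keep]
  pred <- p > threshold
  structure(list(tp = sum(pred & g == 1), fp = sum(pred & g == 0),
                 tn = sum(!pred & g == 0), fn = sum(!pred & g == 1)),
            class = "confusion_counts")
}

#' Segmentation scores from confusion counts
#'
#' Computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)`, recall and F1 (harmonic mean of
#' precision and recall).  A ratio with a zero denominator is returned as
#' `NA` and flagged in the `undefined` attribute rather than silently
#' reported as 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return named list `se`, `sp`, `acc`, `precision`, `recall`, `f1`, with
#'   attribute `undefined` naming any 0/0 metrics.
#' @export
segmentation_scores <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion counts", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  se <- ratio(tp, tp + fn)
  sp <- ratio(tn, tn + fp)
  acc <- (tp + tn) / total
  precision <- ratio(tp, tp + fp)
  recall <- se
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  out <- list(se = se, sp = sp, acc = acc, precision = precision,
              recall = recall, f1 = f1)
  attr(out, "undefined") <- names(out)[vapply(out, is.na, TRUE)]
  out
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the probability that a randomly
#' chosen vessel pixel receives a higher score than a randomly chosen
#' background pixel, with ties counted one half (Mann-Whitney statistic;
#' equal to the trapezoidal ROC area).
#'
#' @param scores numeric vector of prediction scores.
#' @param labels binary vector (0/1) of the same length.
#' @return AUC in `[0, 1]`, or `NA` (flagged via a warning) when only one
#'   class is present.
#' @export
rank_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)                     # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pool evaluation results over a test set
#'
#' Sums confusion counts globally across images before computing scores, and
#' pools all pixels for a single AUC, so one report describes the whole test
#' set.
#'
#' @param probs list of probability matrices.
#' @param gts list of matching binary masks.
#' @param threshold classification threshold (default 0.5).
#' @param mask optional list of logical evaluation-domain masks.
#' @return a `metric_report`: list with `se`, `sp`, `acc`, `precision`,
#'   `recall`, `f1`, `auc`, and the pooled `counts`.
#' @export
pool_metrics <- function(probs, gts, threshold = 0.5, mask = NULL) {
  stopifnot(length(probs) == length(gts))
  if (length(probs) == 0) stop("no images to evaluate", call. = FALSE)
  tp <- fp <- tn <- fn <- 0L
  all_p <- vector("list", length(probs)); all_g <- vector("list", length(probs))
  for (i in seq_along(probs)) {
    mi <- if (is.null(mask)) NULL else mask[[i]]
    cc <- confusion_counts(probs[[i]], gts[[i]], threshold, mi)
    tp <- tp + cc$tp; fp <- fp + cc$fp; tn <- tn + cc$tn; fn <- fn + cc$fn
    keep <- if (is.null(mi)) TRUE else as.logical(mi)
    all_p[[i]] <- probs[[i]][keep]; all_g[[i]] <- gts[[i]][keep]
  }
  counts <- structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
                      class = "confusion_counts")
  rep <- segmentation_scores(counts)
  rep$auc <- rank_auc(unlist(all_p), unlist(all_g))
  rep$counts <- counts
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  v <- c(SE = x$se, SP = x$sp, ACC = x$acc, F1 = x$f1, AUC = x$auc)
  cat("Pixel-level segmentation metrics\n")
  print(round(v, digits))
  invisible(x)
}

#' Write a metrics table
#'
#' Writes one or more metric reports as a delimited text table with the
#' column order SE, SP, ACC, F1, AUC.
#'
#' @param reports named list of `metric_report` objects.
#' @param file path of the tab-separated output file.
#' @return the data frame, invisibly.
#' @export
write_metrics_table <- function(reports, file) {
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, SE = r$se, SP = r$sp, ACC = r$acc, F1 = r$f1,
               AUC = r$auc)
  }))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
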