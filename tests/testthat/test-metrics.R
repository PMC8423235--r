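test_that("confusion counts: perfect prediction, tie rule, shape guard", {
  gt <- random_mask(6, 6)
  cc <- confusion_counts(gt, gt)
  expect_identical(cc$fp + cc$fn, 0L)
  ties <- matrix(0.5, 6, 6)
  ct <- confusion_counts(ties, gt)
  expect_identical(ct$tp + ct$fp, 0L)             # prob == threshold -> background
  expect_error(confusion_counts(matrix(0.5, 4, 4), gt), "shapes")
})

test_that("confusion counts match the exhaustive per-pixel oracle", {
  set.seed(1)
  for (rep in 1:5) {
    prob <- matrix(runif(16), 4, 4)
    gt <- random_mask(4, 4, 0.4)
    cc <- confusion_counts(prob, gt)
    oc <- naive_confusion(prob, gt)
    expect_identical(unclass(cc)[c("tp", "fp", "tn", "fn")],
                     lapply(oc, as.integer))
  }
})

test_that("scores reproduce direct substitution and flag 0/0 cases", {
  cc <- structure(list(tp = 2L, fp = 1L, tn = 5L, fn = 2L),
                  class = "confusion_counts")
  s <- segmentation_scores(cc)
  expect_equal(s$se, 0.5)
  expect_equal(s$precision, 2 / 3)
  expect_equal(s$f1, 4 / 7)
  perfect <- structure(list(tp = 3L, fp = 0L, tn = 7L, fn = 0L),
                       class = "confusion_counts")
  sp <- segmentation_scores(perfect)
  expect_equal(unlist(sp[c("se", "sp", "acc", "f1")]), rep(1, 4),
               ignore_attr = TRUE)
  novessel <- structure(list(tp = 0L, fp = 0L, tn = 9L, fn = 0L),
                        class = "confusion_counts")
  sn <- segmentation_scores(novessel)
  expect_true(is.na(sn$se))
  expect_true("se" %in% attr(sn, "undefined"))
})

test_that("AUC: separable scores give 1, constant scores give 0.5", {
  labels <- c(rep(1, 5), rep(0, 5))
  expect_equal(rank_auc(c(6:10, 1:5), labels), 1)
  expect_equal(rank_auc(rep(0.3, 10), labels), 0.5)
  expect_warning(a <- rank_auc(1:4, rep(1, 4)), "one class")
  expect_true(is.na(a))
})

test_that("AUC equals the O(n^2) pairwise oracle and pROC on random data", {
  set.seed(2)
  for (rep in 1:10) {
    n <- 12
    scores <- round(runif(n), 1)      # coarse grid forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(rank_auc(scores, labels), naive_auc(scores, labels),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- runif(200); labels <- rbinom(200, 1, 0.3)
  expect_equal(rank_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone transforms of the scores", {
  set.seed(4)
  scores <- runif(60); labels <- rbinom(60, 1, 0.4)
  a0 <- rank_auc(scores, labels)
  expect_equal(rank_auc(qlogis(scores), labels), a0, tolerance = 1e-12)
  expect_equal(rank_auc(scores^3 + 2, labels), a0, tolerance = 1e-12)
})

test_that("complementing predictions and labels swaps sensitivity and specificity", {
  set.seed(5)
  prob <- matrix(runif(64), 8, 8)
  gt <- random_mask(8, 8, 0.3)
  s1 <- segmentation_scores(confusion_counts(prob, gt))
  s2 <- segmentation_scores(confusion_counts(1 - prob, 1 - gt, threshold = 0.5))
  # 1 - prob > 0.5 <=> prob < 0.5: ties flip sides, so exclude exact 0.5
  expect_equal(s2$se, s1$sp, tolerance = 1e-12)
  expect_equal(s2$sp, s1$se, tolerance = 1e-12)
})

test_that("F1 is bounded by precision and recall", {
  set.seed(6)
  for (rep in 1:20) {
    cc <- structure(as.list(setNames(rpois(4, 5), c("tp", "fp", "tn", "fn"))),
                    class = "confusion_counts")
    s <- segmentation_scores(cc)
    if (any(is.na(unlist(s)))) next
    expect_lte(s$f1, min(1, 2 * s$precision))
    expect_gte(s$f1, min(s$precision, s$recall) - 1e-12)
    expect_lte(s$f1, max(s$precision, s$recall) + 1e-12)
  }
})

test_that("pooling one image equals its own report; duplicates leave ratios unchanged", {
  set.seed(7)
  prob <- matrix(runif(64), 8, 8); gt <- random_mask(8, 8, 0.3)
  r1 <- pool_metrics(list(prob), list(gt))
  r2 <- pool_metrics(list(prob, prob), list(gt, gt))
  for (k in c("se", "sp", "acc", "f1", "auc"))
    expect_equal(r2[[k]], r1[[k]], tolerance = 1e-12)
  s <- segmentation_scores(confusion_counts(prob, gt))
  expect_equal(r1$f1, s$f1)
})

test_that("pooling two unequal images equals the concatenate-then-score oracle", {
  set.seed(8)
  p1 <- matrix(runif(24), 4, 6); g1 <- random_mask(4, 6, 0.4)
  p2 <- matrix(runif(60), 6, 10); g2 <- random_mask(6, 10, 0.2)
  pooled <- pool_metrics(list(p1, p2), list(g1, g2))
  allp <- c(p1, p2); allg <- c(g1, g2)
  oc <- naive_confusion(allp, allg)
  expect_identical(pooled$counts$tp, as.integer(oc$tp))
  expect_identical(pooled$counts$fn, as.integer(oc$fn))
  expect_equal(pooled$auc, naive_auc(allp, allg), tolerance = 1e-12)
  expect_error(pool_metrics(list(), list()), "no images")
})
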