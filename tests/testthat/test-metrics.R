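test_that("confusion counts match hand-computed toy cases", {
  pred <- matrix(0L, 2, 2); pred[1, 1] <- 1L; pred[1, 2] <- 1L
  gt <- matrix(0L, 2, 2); gt[1, 2] <- 1L; gt[2, 2] <- 1L
  cc <- confusion_counts(binary_mask(pred), binary_mask(gt))
  expect_equal(cc, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  m <- rand_mask(9, 9, seed = 2)
  cc2 <- confusion_counts(binary_mask(m), binary_mask(m))
  expect_equal(cc2$FP, 0L); expect_equal(cc2$FN, 0L)
  n <- 25L
  cc3 <- confusion_counts(matrix(1L, 5, 5), matrix(0L, 5, 5))
  expect_equal(cc3, list(TP = 0L, FP = n, TN = 0L, FN = 0L))
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               class = "emaseg_validation_error")
})

test_that("overlap scores follow the printed formulas and degenerate rules", {
  sc <- overlap_scores(list(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(sc, list(iou = 1/3, dsc = 1/2, rec = 1/2, spe = 1/2, pre = 1/2))
  perfect <- overlap_scores(list(TP = 10, FP = 0, TN = 5, FN = 0))
  expect_true(all(unlist(perfect) == 1))
  # empty reference and empty prediction: vacuously perfect
  e <- overlap_scores(list(TP = 0, FP = 0, TN = 9, FN = 0))
  expect_equal(e$rec, 1); expect_equal(e$pre, 1); expect_equal(e$iou, 1)
  # empty reference but spurious prediction
  s <- overlap_scores(list(TP = 0, FP = 3, TN = 6, FN = 0))
  expect_equal(s$rec, 0); expect_equal(s$iou, 0); expect_equal(s$pre, 0)
})

test_that("overlap scores agree with a brute-force per-pixel oracle", {
  for (s in 1:5) {
    p <- rand_mask(16, 16, p = 0.4, seed = s)
    g <- rand_mask(16, 16, p = 0.35, seed = s + 50)
    cc <- confusion_counts(binary_mask(p), binary_mask(g))
    tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
    for (i in 1:16) for (j in 1:16) {
      if (p[i, j] == 1 && g[i, j] == 1) tp <- tp + 1L
      if (p[i, j] == 1 && g[i, j] == 0) fp <- fp + 1L
      if (p[i, j] == 0 && g[i, j] == 0) tn <- tn + 1L
      if (p[i, j] == 0 && g[i, j] == 1) fn <- fn + 1L
    }
    expect_identical(unlist(cc), c(TP = tp, FP = fp, TN = tn, FN = fn))
    sc <- overlap_scores(cc)
    expect_equal(sc$iou, tp / (tp + fp + fn))
    expect_equal(sc$dsc, 2 * tp / (2 * tp + fp + fn))
    expect_equal(sc$dsc, 2 * sc$iou / (1 + sc$iou), tolerance = 1e-9)
  }
})

test_that("dilating a prediction away from the reference never decreases FP", {
  g <- matrix(0L, 20, 20); g[8:12, 8:12] <- 1L
  p <- g
  prev <- confusion_counts(p, g)$FP
  for (r in 1:3) {
    p2 <- eg$binary_dilate(p, r)
    fp <- confusion_counts(p2, g)$FP
    expect_gte(fp, prev)
    prev <- fp
  }
})

test_that("hd95 matches closed-form toy distances and is symmetric", {
  sq <- matrix(0L, 16, 16); sq[5:10, 5:10] <- 1L
  expect_equal(hd95(sq, sq, c(0.5, 0.5)), 0)
  a <- matrix(0L, 9, 9); a[5, 2] <- 1L
  b <- matrix(0L, 9, 9); b[5, 7] <- 1L
  expect_equal(hd95(a, b, c(0.5, 0.5)), 2.5)
  # 1-px translation at 1 mm/px: brute-force pooled percentile
  t1 <- matrix(0L, 16, 16); t1[5:10, 6:11] <- 1L
  got <- hd95(sq, t1, c(1, 1))
  bp <- eg$boundary_pixels(sq); bq <- eg$boundary_pixels(t1)
  dd <- c(apply(bp, 1, function(r) min(sqrt(colSums((t(bq) - r)^2)))),
          apply(bq, 1, function(r) min(sqrt(colSums((t(bp) - r)^2)))))
  expect_equal(got, as.numeric(quantile(dd, 0.95, type = 7)))
  expect_equal(got, 1.0)
  expect_equal(hd95(sq, t1, c(1, 1)), hd95(t1, sq, c(1, 1)))
  # anisotropic spacing scales row distances differently
  expect_equal(hd95(a, b, c(2, 0.5)), 2.5)
  expect_error(hd95(matrix(0L, 4, 4), sq[1:4, 1:4], c(1, 1)),
               class = "emaseg_validation_error")
})

test_that("hd95 agrees with a brute-force pooled percentile on random blobs", {
  for (s in 1:3) {
    p <- quiet_params(size = 64L)
    m1 <- generate_phantom(p, seed = s)$mask$labels
    m2 <- generate_phantom(p, seed = s + 20)$mask$labels
    got <- hd95(m1, m2, c(0.8, 0.6))
    b1 <- eg$boundary_pixels(m1); b2 <- eg$boundary_pixels(m2)
    sc <- function(bm) cbind(bm[, 1] * 0.8, bm[, 2] * 0.6)
    s1 <- sc(b1); s2 <- sc(b2)
    dd <- c(apply(s1, 1, function(r) min(sqrt(colSums((t(s2) - r)^2)))),
            apply(s2, 1, function(r) min(sqrt(colSums((t(s1) - r)^2)))))
    expect_equal(got, as.numeric(quantile(dd, 0.95, type = 7)), tolerance = 1e-9)
  }
})

test_that("evaluation reports carry per-image rows plus mean and sd", {
  p <- quiet_params(size = 64L)
  masks <- lapply(1:3, function(s) generate_phantom(p, seed = s)$mask)
  preds <- lapply(masks, function(m) binary_mask(eg$binary_dilate(m$labels, 1L), id = m$id))
  d <- withr::local_tempdir()
  rep <- evaluation_report(preds, masks, c(0.8, 0.8), file.path(d, "eval.csv"))
  expect_equal(nrow(rep), 5L)
  expect_equal(rep$id[4:5], c("mean", "sd"))
  expect_equal(names(rep), c("id", "pre", "iou", "rec", "dsc", "hd95_mm"))
  expect_equal(rep$rec[1:3], rep(1, 3))   # dilation covers the reference fully
  expect_true(file.exists(file.path(d, "eval.csv")))
})
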