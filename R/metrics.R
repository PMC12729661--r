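# Pixel-overlap and boundary metrics.

#' Confusion counts between predicted and reference masks
#'
#' @param pred,gt [binary_mask()] objects (or 0/1 matrices) of equal shape.
#' @return list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(pred, gt) {
  p <- if (inherits(pred, "binary_mask")) pred$labels else pred
  g <- if (inherits(gt, "binary_mask")) gt$labels else gt
  if (!all(dim(p) == dim(g))) err_validation("mask shapes differ")
  tp <- sum(p == 1L & g == 1L); fp <- sum(p == 1L & g == 0L)
  tn <- sum(p == 0L & g == 0L); fn <- sum(p == 0L & g == 1L)
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

ratio_or <- function(num, den, vacuous_ok) {
  if (den == 0) return(if (vacuous_ok) 1 else 0)
  num / den
}

#' Overlap scores from confusion counts
#'
#' `IoU = TP/(TP+FP+FN)`, `DSC = 2TP/(2TP+FP+FN)`, `Rec = TP/(TP+FN)`,
#' `Spe = TN/(TN+FP)`, `Pre = TP/(TP+FP)`. A zero denominator returns 1
#' when the metric is vacuously perfect (e.g. recall with no foreground in
#' the reference and none predicted) and 0 otherwise.
#'
#' @param counts list from [confusion_counts()].
#' @return list with `iou`, `dsc`, `rec`, `spe`, `pre`.
#' @export
overlap_scores <- function(counts) {
  with(counts, list(
    iou = ratio_or(TP, TP + FP + FN, TRUE),
    dsc = ratio_or(2 * TP, 2 * TP + FP + FN, TRUE),
    rec = ratio_or(TP, TP + FN, FP == 0),
    spe = ratio_or(TN, TN + FP, FN == 0),
    pre = ratio_or(TP, TP + FP, FN == 0)
  ))
}

boundary_pixels <- function(m) {
  er <- binary_erode(m, 1L)   # 3x3 structuring element (8-connectivity)
  which(m == 1L & er == 0L, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance between mask boundaries (mm)
#'
#' Boundary pixels are the foreground pixels removed by a 3x3 erosion.
#' Directed nearest-boundary distances are pooled from both directions and
#' the 95th percentile (linear interpolation) is taken, under anisotropic
#' pixel spacing. Symmetric by construction.
#'
#' @param pred,gt [binary_mask()] objects (or 0/1 matrices); both must be
#'   non-empty.
#' @param spacing_mm `(row_mm_per_px, col_mm_per_px)`.
#' @return HD95 in millimetres.
#' @export
hd95 <- function(pred, gt, spacing_mm) {
  p <- if (inherits(pred, "binary_mask")) pred$labels else pred
  g <- if (inherits(gt, "binary_mask")) gt$labels else gt
  if (!all(dim(p) == dim(g))) err_validation("mask shapes differ")
  if (sum(p) == 0 || sum(g) == 0)
    err_validation("undefined boundary: empty mask")
  bp <- boundary_pixels(p); bg <- boundary_pixels(g)
  d1 <- .cpp_nn_dist(bp, bg, spacing_mm[1], spacing_mm[2])
  d2 <- .cpp_nn_dist(bg, bp, spacing_mm[1], spacing_mm[2])
  as.numeric(stats::quantile(c(d1, d2), 0.95, type = 7))
}

#' Per-image evaluation report
#'
#' One row per image with Pre, IoU, Rec, DSC and HD95 (mm), plus a summary
#' row holding the mean and a companion row with the standard deviation
#' across images.
#'
#' @param preds,gts lists of [binary_mask()] of equal length.
#' @param spacing_mm pixel spacing used for HD95.
#' @param path optional CSV output path.
#' @return data frame of the report.
#' @export
evaluation_report <- function(preds, gts, spacing_mm, path = NULL) {
  stopifnot(length(preds) == length(gts))
  rows <- lapply(seq_along(preds), function(i) {
    sc <- overlap_scores(confusion_counts(preds[[i]], gts[[i]]))
    hd <- tryCatch(hd95(preds[[i]], gts[[i]], spacing_mm),
                   error = function(e) NA_real_)
    data.frame(id = preds[[i]]$id, pre = sc$pre, iou = sc$iou, rec = sc$rec,
               dsc = sc$dsc, hd95_mm = hd)
  })
  df <- do.call(rbind, rows)
  num <- df[, -1, drop = FALSE]
  summ <- data.frame(id = c("mean", "sd"),
                     rbind(colMeans(num, na.rm = TRUE),
                           apply(num, 2, stats::sd, na.rm = TRUE)))
  names(summ) <- names(df)
  out <- rbind(df, summ)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
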