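# Eye-muscle-area measurement and agreement analysis.
#
# A segmentation mask becomes a physical area by counting foreground
# pixels and multiplying by the per-pixel area from the device calibration
# (row mm/px x col mm/px). Automated areas are then compared against
# expert reference areas with four complementary statistics: MAE (absolute
# accuracy), MAPE (relative accuracy), SEM (signed mean error: systematic
# over-/under-estimation) and Pearson r (linear consistency).

#' Device calibration (mm per pixel along each axis)
#'
#' @param row_mm_per_px,col_mm_per_px positive reals.
#' @return a `calibration` object.
#' @export
calibration <- function(row_mm_per_px, col_mm_per_px = row_mm_per_px) {
  if (row_mm_per_px <= 0 || col_mm_per_px <= 0)
    err_validation("calibration values must be positive")
  structure(list(row_mm_per_px = row_mm_per_px, col_mm_per_px = col_mm_per_px,
                 area_per_pixel = row_mm_per_px * col_mm_per_px),
            class = "calibration")
}

area_record <- function(id, pixel_count, area_mm2) {
  structure(list(id = as.character(id), pixel_count = as.integer(pixel_count),
                 area_mm2 = as.numeric(area_mm2)), class = "area_record")
}

#' Measure the calibrated area of a binary mask
#'
#' @param mask a [binary_mask()].
#' @param cal a [calibration()].
#' @return an `area_record` with `pixel_count` and `area_mm2`.
#' @export
measure_area <- function(mask, cal) {
  if (!inherits(mask, "binary_mask")) err_validation("not a binary mask")
  n <- sum(mask$labels)
  area_record(mask$id, n, n * cal$area_per_pixel)
}

#' Agreement statistics between automated and reference measurements
#'
#' `MAE = mean(|auto - ref|)`, `MAPE = 100 * mean(|auto - ref| / ref)`,
#' `SEM = mean(auto - ref)` (signed; positive means systematic
#' overestimation) and Pearson `r`. Identical lists return r = 1 with
#' `r_degenerate = TRUE` (the 0/0 case resolved in favour of the identity
#' pipeline check); a constant, non-identical list is an error.
#'
#' @param reference numeric vector of reference values (must be nonzero for
#'   MAPE).
#' @param automated numeric vector of automated values, same length (>= 2).
#' @param unit unit tag carried through reporting ("mm2" or "px"); MAE and
#'   SEM are in this unit.
#' @return an `agreement_report` list with `n`, `mae`, `mape`, `sem`, `r`,
#'   `r_degenerate`, `unit`, `mean_bias` and per-method descriptive
#'   statistics (`stats`: mean, sd, min, max).
#' @export
agreement_stats <- function(reference, automated, unit = "mm2") {
  y <- as.numeric(reference); yh <- as.numeric(automated)
  if (length(y) != length(yh)) err_validation("length mismatch")
  if (length(y) < 2L) err_validation("need at least two pairs")
  if (any(y == 0)) err_validation("reference values must be nonzero for MAPE")
  err <- yh - y
  mae <- mean(abs(err))
  mape <- 100 * mean(abs(err) / abs(y))
  sem <- mean(err)
  degenerate <- FALSE
  if (identical(y, yh)) {
    r <- 1; degenerate <- TRUE
  } else if (stats::sd(y) == 0 || stats::sd(yh) == 0) {
    err_validation("undefined correlation: constant measurement list")
  } else {
    r <- stats::cor(y, yh)
  }
  desc <- function(v) c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))
  structure(list(n = length(y), mae = mae, mape = mape, sem = sem, r = r,
                 r_degenerate = degenerate, unit = unit,
                 mean_bias = mean(yh) - mean(y),
                 stats = rbind(reference = desc(y), automated = desc(yh))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over n = %d pairs (%s)\n", x$n, x$unit))
  cat(sprintf("  MAE  = %.4f %s\n  MAPE = %.4f %%\n  SEM  = %+.4f %s\n",
              x$mae, x$unit, x$mape, x$sem, x$unit))
  cat(sprintf("  r    = %.4f%s\n", x$r,
              if (x$r_degenerate) " (degenerate: identical lists)" else ""))
  cat(sprintf("  mean bias = %+.4f %s\n", x$mean_bias, x$unit))
  print(round(x$stats, 2))
  invisible(x)
}

#' Write an agreement report as CSV and JSON
#'
#' @param report an `agreement_report`.
#' @param csv_path,json_path output paths (either may be NULL).
#' @return invisible NULL.
#' @export
write_agreement_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- data.frame(metric = c("n", "mae", "mape_pct", "sem", "r", "mean_bias"),
                     value = c(report$n, report$mae, report$mape, report$sem,
                               report$r, report$mean_bias),
                     unit = c("", report$unit, "%", report$unit, "", report$unit))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      err_io("JSON output requires jsonlite")
    jsonlite::write_json(report[c("n", "mae", "mape", "sem", "r",
                                  "r_degenerate", "unit", "mean_bias")],
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}

#' Bland-Altman-style agreement plot
#'
#' @param reference,automated numeric vectors of paired areas.
#' @param path PNG output path.
#' @return the path, invisibly.
#' @export
agreement_plot <- function(reference, automated, path) {
  grDevices::png(path, width = 700, height = 450)
  on.exit(grDevices::dev.off())
  m <- (reference + automated) / 2; d <- automated - reference
  graphics::plot(m, d, xlab = "mean of methods (mm^2)",
                 ylab = "automated - reference (mm^2)",
                 main = "Agreement of automated vs reference area", pch = 19)
  graphics::abline(h = mean(d), lty = 2)
  graphics::abline(h = mean(d) + c(-1.96, 1.96) * stats::sd(d), lty = 3)
  invisible(path)
}

#' Absolute and relative improvement between two metric values
#'
#' @param metric_a baseline value (must be > 0 for the relative change).
#' @param metric_b improved value.
#' @return list with `absolute_points` (`b - a`) and `relative_percent`
#'   (`100 (b - a)/a`, rounded to two decimals for reporting).
#' @export
improvement_stats <- function(metric_a, metric_b) {
  if (metric_a <= 0) err_validation("baseline must be positive for a relative change")
  list(absolute_points = metric_b - metric_a,
       relative_percent = round(100 * (metric_b - metric_a) / metric_a, 2))
}
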