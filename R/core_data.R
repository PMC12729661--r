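# Data model and I/O: ultrasound frames, binary masks, dataset manifests,
# train/val/test splitting and the run configuration.
#
# Coordinate convention: 0-based concepts, row-major thinking, origin
# top-left; array shapes are (rows = H, cols = W), so a "730 x 660" source
# image (width x height) loads as H = 660, W = 730.

#' Construct an ultrasound frame
#'
#' @param pixels numeric matrix `(H, W)` with values in `[0, 1]`.
#' @param spacing_mm numeric pair `(row_mm_per_px, col_mm_per_px)`.
#' @param id frame identifier.
#' @return an `ultrasound_frame` object.
#' @export
ultrasound_frame <- function(pixels, spacing_mm, id = "frame") {
  if (!is.matrix(pixels) || nrow(pixels) < 32L || ncol(pixels) < 32L)
    err_validation("frame pixels must be a matrix at least 32 x 32")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    err_validation("pixel values must lie in [0, 1]")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    err_validation("spacing_mm must be two positive numbers")
  structure(list(pixels = pixels, spacing_mm = spacing_mm, id = as.character(id)),
            class = "ultrasound_frame")
}

#' Construct a binary mask
#'
#' @param labels matrix of 0/1 labels `(H, W)`.
#' @param id mask identifier.
#' @return a `binary_mask` object.
#' @export
binary_mask <- function(labels, id = "mask") {
  if (!is.matrix(labels)) err_validation("mask labels must be a matrix")
  if (!all(labels %in% c(0, 1))) err_validation("mask values must be 0 or 1")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, id = as.character(id)), class = "binary_mask")
}

rgb_to_luma <- function(a) {
  0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
}

read_image_gray <- function(path) {
  if (!file.exists(path)) err_io(paste("cannot read image:", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    a <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      err_io("JPEG support requires the EBImage package")
    img <- EBImage::readImage(path)
    a <- as.array(img)
    # EBImage stores (x = col, y = row); transpose to (row, col)
    a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  } else {
    err_validation(paste("unsupported image format:", ext))
  }
  if (length(a) == 0L) err_validation("zero-size image")
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) a <- rgb_to_luma(a) else a <- a[, , 1]
  }
  pmin(pmax(a, 0), 1)
}

#' Load an ultrasound frame from a PNG or JPEG file
#'
#' 8-bit (or 16-bit PNG) intensities are rescaled to `[0, 1]`; RGB images
#' are converted to luminance. The frame id is the file stem.
#'
#' @param path image file path.
#' @param spacing_mm `(row_mm_per_px, col_mm_per_px)` calibration of the
#'   acquiring device. Never encoded in the image files themselves, so it
#'   must come from the manifest or configuration.
#' @return an [ultrasound_frame()].
#' @export
load_frame <- function(path, spacing_mm) {
  px <- read_image_gray(path)
  if (!is.matrix(px)) px <- as.matrix(px)
  ultrasound_frame(px, spacing_mm, id = tools::file_path_sans_ext(basename(path)))
}

#' Write a binary mask as a single-channel PNG with values {0, 255}
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask$labels), nrow(mask$labels)), path)
  invisible(path)
}

#' Load a binary mask from PNG (threshold at 128/255)
#'
#' @param path mask PNG path.
#' @return a [binary_mask()].
#' @export
load_mask <- function(path) {
  a <- read_image_gray(path)
  binary_mask((a >= 128 / 255) * 1L, id = tools::file_path_sans_ext(basename(path)))
}

resize_bilinear_matrix <- function(px, H2, W2) {
  Rm <- bilinear_matrix(nrow(px), H2)
  Cm <- bilinear_matrix(ncol(px), W2)
  pmin(pmax(Rm %*% px %*% t(Cm), 0), 1)
}

resize_nearest_matrix <- function(m, H2, W2) {
  ri <- pmin(pmax(floor((seq_len(H2) - 0.5) * nrow(m) / H2) + 1, 1), nrow(m))
  ci <- pmin(pmax(floor((seq_len(W2) - 0.5) * ncol(m) / W2) + 1, 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Resize a frame to the square model input size
#'
#' Bilinear interpolation; the per-axis pixel spacing is rescaled by the
#' resize factor so the physical field of view is preserved exactly.
#'
#' @param frame an [ultrasound_frame()].
#' @param target side length of the square output; must be divisible by 32.
#' @return an [ultrasound_frame()] of size `target x target`.
#' @export
preprocess <- function(frame, target = 512L) {
  if (target %% 32L != 0L) err_validation("target size must be divisible by 32")
  H <- nrow(frame$pixels); W <- ncol(frame$pixels)
  if (H == target && W == target) return(frame)
  px <- resize_bilinear_matrix(frame$pixels, target, target)
  sp <- c(frame$spacing_mm[1] * H / target, frame$spacing_mm[2] * W / target)
  ultrasound_frame(px, sp, id = frame$id)
}

#' Random train/validation/test split
#'
#' Sizes are `floor(n * ratio)` per subset with the remainder assigned to
#' the training set; deterministic for a given seed.
#'
#' @param ids character vector of unique sample ids.
#' @param ratios positive triple summing to one (default `7:2:1`).
#' @param seed integer seed.
#' @return a `split_spec`: list of `train_ids`, `val_ids`, `test_ids`, `seed`.
#' @export
split_dataset <- function(ids, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) err_validation("duplicate ids in split")
  if (length(ratios) != 3L || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9)
    err_validation("ratios must be positive and sum to 1")
  n <- length(ids)
  sizes <- floor(n * ratios)
  sizes[1] <- sizes[1] + (n - sum(sizes))
  perm <- withr::with_seed(seed, sample(ids))
  structure(list(train_ids = perm[seq_len(sizes[1])],
                 val_ids = perm[sizes[1] + seq_len(sizes[2])],
                 test_ids = perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Write a dataset manifest CSV
#'
#' Columns: `id, image_path, mask_path, row_mm_per_px, col_mm_per_px`.
#'
#' @param df data frame with the manifest columns.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(df, path) {
  need <- c("id", "image_path", "mask_path", "row_mm_per_px", "col_mm_per_px")
  if (!all(need %in% names(df))) err_validation("manifest is missing required columns")
  utils::write.csv(df[, need], path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest CSV (relative paths resolved against its folder)
#'
#' @param path manifest CSV path.
#' @return data frame with absolute `image_path` / `mask_path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) err_io(paste("manifest not found:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$image_path <- fix(df$image_path)
  df$mask_path <- fix(df$mask_path)
  df$id <- as.character(df$id)
  df
}

## ---- run configuration ----

#' Default training configuration (full-size model)
#'
#' 50 epochs, batch size 12, AdamW with learning rate 1e-4 and weight decay
#' 5e-2, 512 x 512 inputs, base width 48 with stage depths (2, 2, 2, 2).
#'
#' @param ... named overrides of any field.
#' @return a `run_config` list.
#' @export
default_run_config <- function(...) {
  cfg <- list(epochs = 50L, batch_size = 12L, learning_rate = 1e-4,
              weight_decay = 5e-2, optimizer = "adamw", input_size = 512L,
              base_channels = 48L, stage_depths = c(2L, 2L, 2L, 2L),
              seed = 42L, use_gcad = TRUE, threshold = 0.5,
              augment = default_augment_policy())
  cfg <- utils::modifyList(cfg, list(...))
  validate_run_config(cfg)
}

#' Reduced configuration for CPU-scale experiments
#'
#' Base width 16, one state-space block per stage, 128 x 128 inputs and a
#' larger learning rate (1e-3) suited to short, small-sample runs.
#'
#' @param ... named overrides.
#' @return a `run_config` list.
#' @export
test_profile_config <- function(...) {
  base <- list(epochs = 40L, batch_size = 4L, learning_rate = 1e-3,
               input_size = 128L, base_channels = 16L,
               stage_depths = c(1L, 1L, 1L, 1L))
  do.call(default_run_config, utils::modifyList(base, list(...)))
}

validate_run_config <- function(cfg) {
  if (cfg$epochs <= 0 || cfg$batch_size <= 0)
    err_validation("epochs and batch_size must be positive")
  if (cfg$input_size %% 32L != 0L)
    err_validation("input_size must be divisible by 32")
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file mirroring the `run_config` fields.
#' @return a `run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) err_io(paste("config not found:", path))
  raw <- yaml::read_yaml(path)
  do.call(default_run_config, raw)
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(..., collapse = "")))
}
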