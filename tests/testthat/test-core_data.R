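test_that("frames load from PNG with max-value normalization and file-stem ids", {
  d <- withr::local_tempdir()
  p1 <- file.path(d, "white.png"); p0 <- file.path(d, "black.png")
  png::writePNG(matrix(1, 40, 50), p1)
  png::writePNG(matrix(0, 40, 50), p0)
  f1 <- load_frame(p1, c(0.5, 0.5)); f0 <- load_frame(p0, c(0.5, 0.5))
  expect_true(all(f1$pixels == 1))
  expect_true(all(f0$pixels == 0))
  expect_equal(f1$id, "white")
  expect_equal(dim(f1$pixels), c(40L, 50L))
  expect_error(load_frame(file.path(d, "missing.png"), c(0.5, 0.5)),
               class = "emaseg_io_error")
})

test_that("a 730 x 660 (width x height) image loads as H = 660, W = 730", {
  d <- withr::local_tempdir()
  px <- matrix(runif(660 * 730), 660, 730)
  p <- file.path(d, "wide.png")
  png::writePNG(px, p)
  fr <- load_frame(p, c(0.5, 0.5))
  expect_equal(nrow(fr$pixels), 660L)
  expect_equal(ncol(fr$pixels), 730L)
})

test_that("JPEG frames load through the luminance path", {
  skip_if_not_installed("EBImage")
  d <- withr::local_tempdir()
  p <- file.path(d, "img.jpg")
  px <- matrix(runif(64 * 48), 48, 64)
  suppressWarnings(EBImage::writeImage(EBImage::Image(t(px)), p, quality = 95))
  fr <- load_frame(p, c(0.5, 0.5))
  expect_equal(dim(fr$pixels), c(48L, 64L))
  expect_lt(max(abs(fr$pixels - px)), 0.05)  # lossy codec tolerance
})

test_that("mask write/load round-trips exactly through 0/255 PNG", {
  d <- withr::local_tempdir()
  m <- binary_mask(rand_mask(33, 47, seed = 4))
  p <- file.path(d, "m.png")
  write_mask(m, p)
  m2 <- load_mask(p)
  expect_identical(m2$labels, m$labels)
})

test_that("preprocess preserves the physical field of view", {
  fr <- ultrasound_frame(matrix(runif(660 * 730), 660, 730), c(0.4, 0.3))
  out <- preprocess(fr, 512L)
  expect_equal(dim(out$pixels), c(512L, 512L))
  expect_equal(out$spacing_mm[1], 0.4 * 660 / 512)
  expect_equal(660 * 0.4, 512 * out$spacing_mm[1], tolerance = 1e-6)
  expect_equal(730 * 0.3, 512 * out$spacing_mm[2], tolerance = 1e-6)
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
  # identity case returns the very same pixels
  fr2 <- ultrasound_frame(matrix(runif(512 * 512), 512, 512), c(0.5, 0.5))
  expect_identical(preprocess(fr2, 512L)$pixels, fr2$pixels)
  # constant image stays constant under interpolation
  frc <- ultrasound_frame(matrix(0.5, 100, 80), c(1, 1))
  expect_true(all(abs(preprocess(frc, 64L)$pixels - 0.5) < 1e-12))
  expect_error(preprocess(fr, 100L), class = "emaseg_validation_error")
})

test_that("dataset split honours floor + remainder-to-train and is a partition", {
  ids <- sprintf("s%03d", 1:710)
  sp <- split_dataset(ids, c(0.7, 0.2, 0.1), seed = 3)
  expect_equal(lengths(sp[1:3], use.names = FALSE), c(497L, 142L, 71L))
  expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids), ids)
  expect_identical(sp, split_dataset(ids, c(0.7, 0.2, 0.1), seed = 3))
  sp3 <- split_dataset(c("a", "b", "c"), c(0.7, 0.2, 0.1), seed = 1)
  expect_equal(lengths(sp3[1:3], use.names = FALSE), c(3L, 0L, 0L))
  expect_error(split_dataset(c("a", "a"), seed = 1),
               class = "emaseg_validation_error")
  expect_error(split_dataset(ids, c(0.5, 0.2, 0.1), seed = 1),
               class = "emaseg_validation_error")
})

test_that("manifest round-trips and resolves relative paths", {
  d <- withr::local_tempdir()
  df <- data.frame(id = c("a", "b"), image_path = c("a.png", "b.png"),
                   mask_path = c("a_m.png", "b_m.png"),
                   row_mm_per_px = 0.5, col_mm_per_px = 0.6)
  p <- file.path(d, "manifest.csv")
  write_manifest(df, p)
  back <- read_manifest(p)
  expect_equal(back$id, c("a", "b"))
  expect_true(all(startsWith(back$image_path, normalizePath(d))))
  expect_equal(back$col_mm_per_px, c(0.6, 0.6))
})

test_that("run configuration validates and loads from YAML", {
  cfg <- default_run_config()
  expect_equal(cfg$epochs, 50L)
  expect_equal(cfg$batch_size, 12L)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$weight_decay, 5e-2)
  expect_equal(cfg$optimizer, "adamw")
  expect_error(default_run_config(input_size = 100L),
               class = "emaseg_validation_error")
  expect_error(default_run_config(epochs = 0L),
               class = "emaseg_validation_error")
  d <- withr::local_tempdir()
  yaml::write_yaml(list(epochs = 3, input_size = 64, base_channels = 8),
                   file.path(d, "cfg.yaml"))
  cfg2 <- load_run_config(file.path(d, "cfg.yaml"))
  expect_equal(cfg2$epochs, 3)
  expect_equal(cfg2$input_size, 64)
})
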