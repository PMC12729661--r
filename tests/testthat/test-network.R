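test_that("hybrid loss reproduces hand-computed values", {
  g <- c(1, 1, 0, 0)
  # perfect prediction: both terms vanish up to clipping effects
  l <- total_loss(g, g)
  expect_lt(l$l_dice, 1e-5)
  expect_lt(l$l_bce, 1e-5)
  # total miss: no overlap
  l2 <- total_loss(1 - g, g)
  expect_equal(l2$l_dice, 1, tolerance = 1e-4)
  # hand evaluation: dice = 1 - 2*1/(2+1)
  l3 <- total_loss(c(1, 0, 0, 0), g)
  expect_equal(l3$l_dice, 1 - 2 / 3, tolerance = 1e-4)
  expect_equal(l3$l_total, l3$l_dice + l3$l_bce)
  expect_error(total_loss(c(1, 0), g), class = "emaseg_validation_error")
})

test_that("the total is exactly dice + bce and dice is pixel-permutation-invariant", {
  withr::with_seed(8, {
    p <- runif(100); g <- as.numeric(runif(100) < 0.4)
  })
  l <- total_loss(p, g)
  expect_identical(l$l_total, l$l_dice + l$l_bce)
  perm <- withr::with_seed(9, sample(100))
  l2 <- total_loss(p[perm], g[perm])
  expect_equal(l$l_dice, l2$l_dice, tolerance = 1e-12)
  expect_equal(l$l_bce, l2$l_bce, tolerance = 1e-12)
})

test_that("the differentiable loss agrees with the array-level formulas", {
  withr::with_seed(3, {
    z <- array(rnorm(64), dim = c(8, 8, 1))
    g <- matrix(as.integer(runif(64) < 0.5), 8, 8)
  })
  ls <- eg$loss_ag(eg$ag_const(z), g)
  ref <- total_loss(1 / (1 + exp(-z[, , 1])), g)
  expect_equal(ls$dice$v, ref$l_dice, tolerance = 1e-9)
  expect_equal(ls$bce$v, ref$l_bce, tolerance = 1e-6)
})

test_that("augmentation is the identity at zero probability and deterministic", {
  p <- quiet_params()
  ph <- generate_phantom(p, seed = 14)
  a <- augment_sample(ph$frame, ph$mask, zero_augment(), seed = 5)
  expect_identical(a$frame$pixels, ph$frame$pixels)
  expect_identical(a$mask$labels, ph$mask$labels)
  pol <- default_augment_policy(p_rotate = 1, p_noise = 1)
  b1 <- augment_sample(ph$frame, ph$mask, pol, seed = 7)
  b2 <- augment_sample(ph$frame, ph$mask, pol, seed = 7)
  expect_identical(b1$frame$pixels, b2$frame$pixels)
  expect_identical(b1$mask$labels, b2$mask$labels)
  expect_false(identical(b1$frame$pixels, ph$frame$pixels))
  expect_true(all(b1$mask$labels %in% c(0L, 1L)))
  expect_error(default_augment_policy(p_rotate = 1.4),
               class = "emaseg_validation_error")
})

test_that("an exact quarter-turn permutes mask pixels without changing the count", {
  m <- generate_phantom(quiet_params(), seed = 15)$mask$labels
  H <- nrow(m); W <- ncol(m)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  R <- matrix(rep(seq_len(H), W), H) - cy
  C <- matrix(rep(seq_len(W), each = H), H) - cx
  ca <- cos(pi / 2); sa <- sin(pi / 2)
  rr <- ca * R - sa * C + cy
  cc <- sa * R + ca * C + cx
  rot <- eg$sample_nearest(m, rr, cc)
  expect_equal(sum(rot), sum(m))
  expect_true(all(rot %in% c(0L, 1L)))
})

test_that("training runs, logs per-epoch history and is seed-deterministic", {
  d <- withr::local_tempdir()
  man <- generate_dataset(2, phantom_params(size = 96L, spacing_mm = c(0.9, 0.9)), file.path(d, "ph"), seed = 3)
  df <- read_manifest(man)
  split <- list(train_ids = df$id, val_ids = character(0), test_ids = character(0))
  cfg <- tiny_config(epochs = 1L, batch_size = 2L, input_size = 96L, seed = 19L)
  r1 <- train_model(cfg, df, split = split, out_dir = file.path(d, "run"))
  expect_equal(nrow(r1$history), 1L)
  expect_true(file.exists(file.path(d, "run", "history.csv")))
  expect_true(file.exists(file.path(d, "run", "best.ckpt")))
  r2 <- train_model(cfg, df, split = split)
  expect_equal(r1$history$train_loss, r2$history$train_loss, tolerance = 1e-12)
  expect_error(train_model(cfg, df, split = list(train_ids = character(0),
                                                 val_ids = df$id,
                                                 test_ids = character(0))),
               class = "emaseg_validation_error")
})

test_that("prediction yields a binary mask on the native grid with threshold extremes", {
  cfg <- tiny_config(input_size = 96L, base_channels = 8L, seed = 23L)
  model <- build_model(cfg)
  ph <- generate_phantom(phantom_params(size = 120L, spacing_mm = c(0.85, 0.85)),
                         seed = 40)
  pr <- predict_mask(model, ph$frame)
  expect_s3_class(pr, "binary_mask")
  expect_equal(dim(pr$labels), dim(ph$frame$pixels))
  expect_true(all(pr$labels %in% c(0L, 1L)))
  expect_true(all(predict_mask(model, ph$frame, threshold = 0)$labels == 1L))
  expect_true(all(predict_mask(model, ph$frame, threshold = 1)$labels == 0L))
})

test_that("checkpoints round-trip weights exactly", {
  d <- withr::local_tempdir()
  cfg <- tiny_config(input_size = 96L, base_channels = 8L, seed = 29L)
  model <- build_model(cfg)
  p <- file.path(d, "m.ckpt")
  save_checkpoint(model, p)
  back <- load_checkpoint(p)
  ph <- generate_phantom(phantom_params(size = 96L, spacing_mm = c(0.9, 0.9)), seed = 41)
  expect_identical(predict_mask(model, ph$frame)$labels,
                   predict_mask(back, ph$frame)$labels)
  expect_error(load_checkpoint(file.path(d, "missing.ckpt")),
               class = "emaseg_io_error")
})
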