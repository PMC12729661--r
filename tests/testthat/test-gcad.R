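make_gcad <- function(ch = 6L, seed = 5) withr::with_seed(seed, eg$gcad_init(ch))

test_that("the concatenated MCA feature set has width 4C", {
  for (ch in c(4L, 10L)) {
    w <- make_gcad(ch, seed = ch)
    x <- eg$ag_const(rand_arr(12, 12, ch, seed = 1))
    f1 <- eg$with_no_grad(eg$fwd_dsconv(w$dwc6, x, dil = 6L))
    f2 <- eg$with_no_grad(eg$fwd_dsconv(w$dwc4, eg$ag_add(x, f1), dil = 4L))
    f3 <- eg$with_no_grad(eg$fwd_dsconv(w$dwc2, eg$ag_add(x, f2), dil = 2L))
    f4 <- eg$with_no_grad(eg$avgpool3_ag(x))
    xcon <- eg$with_no_grad(eg$ag_concat_ch(list(x, f2, f3, eg$ag_add(f1, f4))))
    expect_equal(dim(xcon$v)[3], 4L * ch)
  }
})

test_that("the average-pooling branch passes constants through unchanged", {
  x <- eg$ag_const(array(1.3, dim = c(9, 9, 4)))
  out <- eg$with_no_grad(eg$avgpool3_ag(x)$v)
  expect_equal(out, array(1.3, dim = c(9, 9, 4)), tolerance = 1e-12)
})

test_that("a closed gate collapses MCA to the fusion bias", {
  w <- make_gcad(5L)
  w$gate_a$w$v[] <- 0; w$gate_a$b$v[] <- 0
  x <- rand_arr(10, 10, 5, seed = 3)
  out <- mca_forward(w, x)
  ref <- array(rep(w$gate_out$b$v, each = 100), dim = c(10, 10, 5))
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("zero MCA and MLP updates reduce the block to Norm(x)", {
  w <- make_gcad(6L)
  w$gate_out$w$v[] <- 0; w$gate_out$b$v[] <- 0
  w$mlp_out$w$v[] <- 0; w$mlp_out$b$v[] <- 0
  x <- rand_arr(8, 8, 6, seed = 4)
  got <- gcad_block(w, x)
  ref <- eg$with_no_grad(eg$fwd_ln(w$norm1, eg$ag_const(x))$v)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("decoder block output matches a literal step-by-step oracle", {
  ch <- 8L
  w <- make_gcad(ch, seed = 9)
  x <- rand_arr(8, 8, ch, seed = 10)
  got <- gcad_block(w, x)

  ln_ref <- function(l, x) {
    d <- dim(x); m <- matrix(x, d[1] * d[2], d[3])
    mu <- rowMeans(m); xc <- m - mu
    xh <- xc / sqrt(rowMeans(xc^2) + 1e-6)
    array(sweep(sweep(xh, 2, l$g$v, `*`), 2, l$b$v, `+`), dim = d)
  }
  dsc_ref <- function(l, x, dil) {
    C <- dim(x)[3]; kh <- 3
    dwk <- array(0, dim = c(kh, kh, C, C))
    for (c in 1:C) dwk[, , c, c] <- l$dw$w$v[, , c]
    h <- conv_ref(x, dwk, pad = dil, dil = dil)
    sweep(conv_ref(h, l$pw$w$v), 3, l$pw$b$v, `+`)
  }
  conv1_ref <- function(l, x) sweep(conv_ref(x, l$w$v), 3, l$b$v, `+`)
  silu <- function(x) x / (1 + exp(-x))
  gelu <- function(x) x * stats::pnorm(x)
  pool_ref <- function(x) {
    d <- dim(x); out <- array(0, dim = d)
    ri <- function(i, n) pmin(pmax(i, 1), n)
    for (c in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      acc <- 0
      for (di in -1:1) for (dj in -1:1)
        acc <- acc + x[ri(i + di, d[1]), ri(j + dj, d[2]), c]
      out[i, j, c] <- acc / 9
    }
    out
  }
  xa <- ln_ref(w$norm1, x)
  f1 <- dsc_ref(w$dwc6, xa, 6)
  f2 <- dsc_ref(w$dwc4, xa + f1, 4)
  f3 <- dsc_ref(w$dwc2, xa + f2, 2)
  f4 <- pool_ref(xa)
  xcon <- array(c(xa, f2, f3, f1 + f4), dim = c(8, 8, 4 * ch))
  pa <- silu(conv1_ref(w$gate_a, xcon)); pb <- silu(conv1_ref(w$gate_b, xcon))
  xmca <- conv1_ref(w$gate_out, pa * pb)
  xs1 <- xa + ln_ref(w$norm2, xmca)
  y <- xs1 + conv1_ref(w$mlp_out, gelu(conv1_ref(w$mlp_in, xs1)))
  expect_lt(max(abs(got - y)), 1e-6)
  expect_equal(dim(got), dim(x))
})

test_that("decode reconstructs full-resolution logits through the channel ladder", {
  model <- build_model(tiny_config())
  ph <- generate_phantom(phantom_params(), seed = 31)
  pyr <- encode(model, ph$frame)
  logits <- decode(model, pyr)
  expect_equal(dim(logits), c(128L, 128L, 1L))
  expect_true(all(is.finite(logits)))
  # stage fusion convs map 2C -> C along the ladder
  ch <- model$encoder$channels
  for (s in 1:4) {
    expect_equal(dim(model$decoder$stages[[s]]$fuse$w$v)[3:4],
                 c(2L * ch[s], ch[s]))
    expect_equal(model$decoder$stages[[s]]$gcad$ch, ch[s])
  }
  expect_error(decode(model, pyr, bottleneck = rand_arr(2, 2, 256)),
               class = "emaseg_validation_error")
  bad <- pyr; bad[[3]] <- bad[[3]][, , 1:10]
  expect_error(decode(model, bad), class = "emaseg_validation_error")
})

test_that("the decoder still runs with its refinement blocks ablated", {
  model <- build_model(tiny_config(use_gcad = FALSE))
  expect_null(model$decoder$stages[[1]]$gcad)
  ph <- generate_phantom(phantom_params(), seed = 32)
  pyr <- encode(model, ph$frame)
  logits <- decode(model, pyr)
  expect_equal(dim(logits), c(128L, 128L, 1L))
  expect_true(all(is.finite(logits)))
})

test_that("decoded logits stay finite across random phantoms", {
  model <- build_model(tiny_config())
  for (s in c(101, 202, 303, 404, 505)) {
    ph <- generate_phantom(phantom_params(), seed = s)
    logits <- eg$with_no_grad(
      eg$model_forward_ag(model, ph$frame$pixels, training = FALSE)$v)
    expect_true(all(is.finite(logits)))
  }
})
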