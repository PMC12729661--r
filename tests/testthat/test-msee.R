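make_msee <- function(ch = 6L, seed = 4) withr::with_seed(seed, eg$msee_init(ch))

test_that("multiscale context preserves shape and sums four branches", {
  w <- make_msee(6L)
  x <- rand_arr(20, 20, 6, seed = 1)
  expect_equal(dim(multiscale_context(w, x)), dim(x))
  # identity-equivalent kernels: center tap one, zero bias -> LN(4 x)
  w$ctx1$w$v[] <- 0; w$ctx1$b$v[] <- 0
  for (i in 1:6) w$ctx1$w$v[1, 1, i, i] <- 1
  for (k in 1:3) {
    w$dil[[k]]$w$v[] <- 0; w$dil[[k]]$b$v[] <- 0
    for (i in 1:6) w$dil[[k]]$w$v[2, 2, i, i] <- 1
  }
  got <- multiscale_context(w, x)
  ref <- eg$with_no_grad(eg$fwd_ln(w$norm, eg$ag_const(4 * x))$v)
  expect_equal(got, ref, tolerance = 1e-12)
  # zeros map to zeros before the affine normalization shift
  w$norm$g$v[] <- 1; w$norm$b$v[] <- 0
  z <- multiscale_context(w, array(0, dim = c(20, 20, 6)))
  expect_true(all(z == 0))
})

test_that("channel attention rows are softmax-normalized and shift-invariant", {
  w <- make_msee(5L)
  y <- rand_arr(7, 9, 5, seed = 8)
  d <- dim(y); hw <- d[1] * d[2]
  Q <- t(matrix(eg$with_no_grad(eg$fwd_dsconv(w$q, eg$ag_const(y))$v), hw, 5))
  K <- t(matrix(eg$with_no_grad(eg$fwd_dsconv(w$k, eg$ag_const(y))$v), hw, 5))
  lam <- eg$with_no_grad(eg$ag_softmax_rows(
    eg$ag_scale_p(eg$ag_matmul(eg$ag_const(K), eg$ag_const(t(Q))), w$temp))$v)
  expect_equal(rowSums(lam), rep(1, 5), tolerance = 1e-6)
  # shift invariance of softmax over the key logits
  lam2 <- eg$with_no_grad(eg$ag_softmax_rows(
    eg$ag_const(K %*% t(Q) * as.numeric(w$temp$v) + 17))$v)
  expect_equal(lam, lam2, tolerance = 1e-9)
})

test_that("single-channel attention degenerates to the V path", {
  w <- make_msee(1L)
  y <- rand_arr(6, 6, 1, seed = 2)
  got <- transpose_attention(w, y)
  V <- eg$with_no_grad(eg$fwd_dsconv(w$v, eg$ag_const(y))$v)
  ref <- eg$with_no_grad(eg$fwd_dsconv(w$proj, eg$ag_const(V))$v)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("transpose attention matches a literal matrix-product oracle", {
  w <- make_msee(4L)
  y <- rand_arr(8, 8, 4, seed = 5)
  got <- transpose_attention(w, y)
  # step-by-step oracle with plain matrix algebra and loop convolutions
  dsc <- function(l, x, dil = 1) {
    kh <- dim(l$dw$w$v)[1]
    xp <- x
    pad <- as.integer(dil * (kh - 1) / 2)
    C <- dim(x)[3]
    dwk <- array(0, dim = c(kh, kh, C, C))
    for (c in 1:C) dwk[, , c, c] <- l$dw$w$v[, , c]
    h <- conv_ref(x, dwk, pad = pad, dil = dil)
    pw <- conv_ref(h, l$pw$w$v)
    sweep(pw, 3, l$pw$b$v, `+`)
  }
  Q <- dsc(w$q, y, 1); K <- dsc(w$k, y, 1); V <- dsc(w$v, y, 1)
  hw <- 64
  Qh <- t(matrix(Q, hw, 4)); Kh <- t(matrix(K, hw, 4)); Vh <- t(matrix(V, hw, 4))
  logits <- (Kh %*% t(Qh)) * as.numeric(w$temp$v)
  lam <- exp(logits - apply(logits, 1, max))
  lam <- lam / rowSums(lam)
  agg <- array(t(lam %*% Vh), dim = dim(y))
  ref <- dsc(w$proj, agg, 1)
  expect_lt(max(abs(got - ref)), 1e-6)
})

test_that("sobel magnitude vanishes on constants and peaks at a step edge", {
  const <- array(0.7, dim = c(10, 12, 3))
  expect_true(all(sobel_magnitude(const) == 0))
  # vertical step of height s: |Gx| = 4 s on the two columns flanking the step
  s <- 0.6
  step <- array(0, dim = c(8, 8, 1)); step[, 5:8, 1] <- s
  mag <- sobel_magnitude(step)
  expect_equal(max(mag), 4 * s, tolerance = 1e-12)
  expect_true(all(abs(mag[, 4:5, 1] - 4 * s) < 1e-12))
  expect_true(all(mag[, c(1:2, 7:8), 1] < 1e-9))
})

test_that("edge branch reduces to a residual projection when the edge term is zeroed", {
  w <- make_msee(5L)
  x <- rand_arr(9, 9, 5, seed = 3)
  w$e_conv$pw$w$v[] <- 0; w$e_conv$pw$b$v[] <- 0
  got <- edge_branch(w, x)
  ref <- eg$with_no_grad(eg$fwd_dsconv(w$e_out, eg$ag_const(x))$v)
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("the module output is the exact sum of its two paths", {
  for (ch in c(4L, 8L)) {
    w <- make_msee(ch, seed = ch)
    x <- rand_arr(16, 16, ch, seed = ch + 1)
    ef <- transpose_attention(w, multiscale_context(w, x))
    es <- edge_branch(w, x, training = FALSE)
    expect_identical(msee_forward(w, x, training = FALSE), ef + es)
  }
})

test_that("skip-level shape contracts hold and adversarial input stays finite", {
  skip_dims <- list(c(24L, 24L, 8L), c(12L, 12L, 16L))
  for (sd in skip_dims) {
    w <- make_msee(sd[3])
    x <- rand_arr(sd[1], sd[2], sd[3], seed = 9)
    expect_equal(dim(msee_forward(w, x)), sd)
  }
  w <- make_msee(4L)
  chk <- array(rep_len(c(1, -1), 14 * 14 * 4), dim = c(14, 14, 4))
  expect_true(all(is.finite(msee_forward(w, chk))))
})

test_that("a bright boundary ring strictly increases the edge response on the ring", {
  p <- quiet_params()
  ph <- generate_phantom(p, seed = 6)
  px <- ph$frame$pixels
  m <- ph$mask$labels
  ring <- eg$binary_dilate(m, 1L) - eg$binary_erode(m, 1L)
  # identity-configured edge branch front end: the response is the Sobel
  # magnitude of the image itself
  base <- sobel_magnitude(array(px, dim = c(dim(px), 1)))
  px2 <- pmin(px + 0.3 * ring, 1)
  bright <- sobel_magnitude(array(px2, dim = c(dim(px), 1)))
  expect_gt(mean(bright[, , 1][ring == 1]), mean(base[, , 1][ring == 1]))
  # and the full branch output does respond on the ring pixels
  w <- make_msee(1L)
  b0 <- edge_branch(w, array(px, dim = c(dim(px), 1)))
  b1 <- edge_branch(w, array(px2, dim = c(dim(px), 1)))
  expect_gt(max(abs((b1 - b0)[, , 1][ring == 1])), 0)
})
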