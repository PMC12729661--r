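# Shared fixtures. Everything is generated in code; small sizes keep the
# suite CPU-friendly.

eg <- asNamespace("emaseg")

rand_arr <- function(..., seed = 1) {
  d <- c(...)
  withr::with_seed(seed, array(stats::rnorm(prod(d)), dim = d))
}

rand_mask <- function(h, w, p = 0.3, seed = 1) {
  withr::with_seed(seed, matrix(as.integer(stats::runif(h * w) < p), h, w))
}

# a small, quiet phantom configuration used across tests
quiet_params <- function(...) {
  base <- list(size = 96L, spacing_mm = c(0.8, 0.8),
               area_range_mm2 = c(400, 900), feather_sigma = 0,
               speckle_strength = 0, rim_break_prob = 0,
               artifact_range = c(0L, 0L))
  do.call(phantom_params, utils::modifyList(base, list(...)))
}

# direct (loop-based) convolution oracles, independent of the C++ kernels
conv_ref <- function(x, w, stride = 1, pad = 0, dil = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dil * (kw - 1) - 1) %/% stride + 1
  y <- array(0, dim = c(Ho, Wo, Cout))
  for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- 0
    for (ci in 1:Cin) for (dh in 1:kh) for (dw in 1:kw) {
      hi <- (ho - 1) * stride - pad + (dh - 1) * dil + 1
      wi <- (wo - 1) * stride - pad + (dw - 1) * dil + 1
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, ci] * w[dh, dw, ci, co]
    }
    y[ho, wo, co] <- acc
  }
  y
}

# sequential per-pixel selective-scan oracle (plain R loops)
scan_ref <- function(u, de, A, B, Cc, D) {
  d <- nrow(u); L <- ncol(u); N <- ncol(A)
  y <- matrix(0, d, L); h <- matrix(0, d, N)
  for (t in seq_len(L)) for (i in seq_len(d)) {
    for (n in seq_len(N))
      h[i, n] <- exp(de[i, t] * A[i, n]) * h[i, n] + de[i, t] * B[n, t] * u[i, t]
    y[i, t] <- sum(Cc[, t] * h[i, ]) + D[i] * u[i, t]
  }
  y
}

# run the package ss2d weights through the sequential oracle
ss2d_ref <- function(w, x) {
  d <- dim(x)
  L <- d[1] * d[2]
  u0 <- t(matrix(x, L, d[3]))
  ords <- eg$scan_orders(d[1], d[2])
  out <- matrix(0, nrow(u0), L)
  for (k in 1:4) {
    pk <- w$dirs[[k]]
    uk <- u0[, ords[[k]], drop = FALSE]
    dbl <- pk$x_proj$v %*% uk
    dts <- dbl[seq_len(w$R), , drop = FALSE]
    Bm <- dbl[w$R + seq_len(w$N), , drop = FALSE]
    Cm <- dbl[w$R + w$N + seq_len(w$N), , drop = FALSE]
    delta <- log1p(exp(pk$dt_w$v %*% dts + pk$dt_b$v))
    A <- -exp(pk$A_log$v)
    yk <- scan_ref(uk, delta, A, Bm, Cm, pk$D$v)
    out <- out + yk[, order(ords[[k]]), drop = FALSE]
  }
  array(t(out), dim = d)
}

zero_augment <- function() {
  default_augment_policy(p_rotate = 0, p_scale = 0, p_elastic = 0,
                         p_brightness = 0, p_contrast = 0, p_noise = 0)
}

tiny_config <- function(...) {
  test_profile_config(augment = zero_augment(), ...)
}
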