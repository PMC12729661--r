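# Multi-scale edge-enhanced skip module.
#
# Two parallel paths. The context path fuses a 1x1 convolution with three
# 3x3 dilated convolutions (rates 6/12/18) by element-wise summation,
# normalizes, and applies transposed (channel-to-channel) attention built
# from depthwise-separable Q/K/V generators. The edge path sharpens
# boundaries with a fixed Sobel operator inside a small convolutional
# sandwich and a residual connection. The module output is the element-wise
# sum of the two paths.

# Sobel gradient magnitude, depthwise, replicate padding. Each 3x3 Sobel
# kernel is applied separably with the difference stage first, so a
# constant image yields exactly zero (the difference of equal values
# cancels exactly in floating point), borders included.
sobel_magnitude_ag <- function(x) {
  ch <- dim(x$v)[3]
  dx <- ag_const(aperm(array(rep(c(-1, 0, 1), ch), dim = c(3, ch, 1)), c(3, 1, 2)))
  dyk <- ag_const(aperm(array(rep(c(-1, 0, 1), ch), dim = c(3, ch, 1)), c(1, 3, 2)))
  sxk <- ag_const(aperm(array(rep(c(1, 2, 1), ch), dim = c(3, ch, 1)), c(3, 1, 2)))
  syk <- ag_const(aperm(array(rep(c(1, 2, 1), ch), dim = c(3, ch, 1)), c(1, 3, 2)))
  xp <- ag_pad_replicate(x, 1L)
  gx <- ag_dwconv2d(ag_dwconv2d(xp, dx, NULL), syk, NULL)    # d/dx then smooth rows
  gy <- ag_dwconv2d(ag_dwconv2d(xp, dyk, NULL), sxk, NULL)   # d/dy then smooth cols
  ag_sqrt_guard(ag_add(ag_mul(gx, gx), ag_mul(gy, gy)))
}

msee_init <- function(ch) {
  list(
    ctx1 = nn_conv(1L, ch, ch),
    dil = lapply(c(6L, 12L, 18L), function(r) nn_conv(3L, ch, ch)),
    rates = c(6L, 12L, 18L),
    norm = nn_layernorm(ch),
    q = nn_dsconv(3L, ch, ch), k = nn_dsconv(3L, ch, ch), v = nn_dsconv(3L, ch, ch),
    temp = ag_param(1),
    proj = nn_dsconv(1L, ch, ch),
    e_in = nn_dsconv(1L, ch, ch),
    e_bn = nn_batchnorm(ch),
    e_conv = nn_dsconv(3L, ch, ch),
    e_out = nn_dsconv(1L, ch, ch),
    ch = ch
  )
}

mctx_fwd <- function(w, x) {
  s <- fwd_conv(w$ctx1, x, pad = 0L)
  for (i in 1:3) s <- ag_add(s, fwd_conv(w$dil[[i]], x, dil = w$rates[i]))
  fwd_ln(w$norm, s)
}

tattn_fwd <- function(w, y) {
  d <- dim(y$v); hw <- d[1] * d[2]; ch <- d[3]
  Q <- ag_t(ag_reshape(fwd_dsconv(w$q, y), c(hw, ch)))   # C x HW
  K <- ag_t(ag_reshape(fwd_dsconv(w$k, y), c(hw, ch)))
  V <- ag_t(ag_reshape(fwd_dsconv(w$v, y), c(hw, ch)))
  lam <- ag_softmax_rows(ag_scale_p(ag_matmul(K, ag_t(Q)), w$temp))  # C x C
  agg <- ag_reshape(ag_t(ag_matmul(lam, V)), d)
  fwd_dsconv(w$proj, agg)
}

edge_fwd <- function(w, x, training = TRUE) {
  e <- fwd_dsconv(w$e_in, x)
  e <- ag_relu(fwd_bn(w$e_bn, sobel_magnitude_ag(e), training = training))
  xedge <- fwd_dsconv(w$e_conv, e)
  fwd_dsconv(w$e_out, ag_add(x, xedge))
}

msee_fwd <- function(w, x, training = TRUE) {
  ag_add(tattn_fwd(w, mctx_fwd(w, x)), edge_fwd(w, x, training = training))
}

## ---- exported array-level surface ----

#' Multi-scale dilated context fusion
#'
#' Element-wise sum of a 1x1 convolution and three 3x3 dilated convolutions
#' (rates 6, 12, 18), followed by channel layer normalization.
#'
#' @param weights an MSEE weight list (one element of `model$msee`).
#' @param x numeric array `(H, W, C)`.
#' @return numeric array `(H, W, C)`.
#' @export
multiscale_context <- function(weights, x) {
  with_no_grad(mctx_fwd(weights, ag_const(x))$v)
}

#' Transposed (channel) attention over a fused context map
#'
#' Q/K/V are depthwise-separable convolutions of the input; the C x C
#' attention map is `softmax(K Q^T * tau)` with rows summing to one; the
#' output is the attention-weighted V, projected by a 1x1
#' depthwise-separable convolution.
#'
#' @inheritParams multiscale_context
#' @return numeric array `(H, W, C)`.
#' @export
transpose_attention <- function(weights, x) {
  check_finite(x, "attention input")
  with_no_grad(tattn_fwd(weights, ag_const(x))$v)
}

#' Sobel edge-enhancement path
#'
#' `es = DConv1x1(x + DConv3x3(ReLU(BN(Sobel(DConv1x1(x))))))`; the Sobel
#' magnitude uses replicate padding so constant inputs give exactly zero.
#'
#' @inheritParams multiscale_context
#' @param training logical; batch-norm uses spatial statistics when `TRUE`,
#'   running statistics otherwise.
#' @return numeric array `(H, W, C)`.
#' @export
edge_branch <- function(weights, x, training = TRUE) {
  check_finite(x, "edge input")
  with_no_grad(edge_fwd(weights, ag_const(x), training = training)$v)
}

#' Edge-enhanced skip connection forward pass (context path + edge path)
#'
#' @inheritParams edge_branch
#' @return numeric array `(H, W, C)`.
#' @export
msee_forward <- function(weights, x, training = TRUE) {
  check_finite(x, "msee input")
  with_no_grad(msee_fwd(weights, ag_const(x), training = training)$v)
}

#' Sobel gradient magnitude of a feature map
#'
#' @param x numeric array `(H, W, C)`.
#' @return numeric array `(H, W, C)` of per-channel gradient magnitudes.
#' @export
sobel_magnitude <- function(x) {
  with_no_grad(sobel_magnitude_ag(ag_const(x))$v)
}
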