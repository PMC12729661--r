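# Context-aggregation decoder.
#
# Each decoder block wraps a hierarchical dilated depthwise aggregation
# (MCA) in a pre-norm residual + MLP structure:
#   XA = Norm(x); XS1 = XA + Norm(MCA(XA)); Y = XS1 + MLP(XS1).
# Inside MCA, three 3x3 depthwise-separable convolutions with dilations
# 6/4/2 are chained hierarchically, a stride-1 3x3 average pooling branch
# (replicate-padded, so constants pass through unchanged) runs in parallel,
# the four maps are concatenated to width 4C and fused by a multiplicative
# SiLU gate. The decoder ladder upsamples 2x per stage (transposed
# convolution with channel halving), concatenates the edge-enhanced skip,
# fuses with a 1x1 convolution and applies the decoder block.

gcad_init <- function(ch, mlp_ratio = 4L) {
  list(
    norm1 = nn_layernorm(ch),
    dwc6 = nn_dsconv(3L, ch, ch), dwc4 = nn_dsconv(3L, ch, ch),
    dwc2 = nn_dsconv(3L, ch, ch),
    gate_a = nn_conv(1L, 4L * ch, ch), gate_b = nn_conv(1L, 4L * ch, ch),
    gate_out = nn_conv(1L, ch, ch),
    norm2 = nn_layernorm(ch),
    mlp_in = nn_conv(1L, ch, mlp_ratio * ch), mlp_out = nn_conv(1L, mlp_ratio * ch, ch),
    ch = ch
  )
}

avgpool3_ag <- function(x) {
  ch <- dim(x$v)[3]
  k <- ag_const(array(1 / 9, dim = c(3, 3, ch)))
  ag_dwconv2d(ag_pad_replicate(x, 1L), k, NULL, stride = 1L, pad = 0L)
}

mca_fwd <- function(w, xa) {
  f1 <- fwd_dsconv(w$dwc6, xa, dil = 6L)
  f2 <- fwd_dsconv(w$dwc4, ag_add(xa, f1), dil = 4L)
  f3 <- fwd_dsconv(w$dwc2, ag_add(xa, f2), dil = 2L)
  f4 <- avgpool3_ag(xa)
  xcon <- ag_concat_ch(list(xa, f2, f3, ag_add(f1, f4)))
  pa <- ag_silu(fwd_conv(w$gate_a, xcon, pad = 0L))
  pb <- ag_silu(fwd_conv(w$gate_b, xcon, pad = 0L))
  fwd_conv(w$gate_out, ag_mul(pa, pb), pad = 0L)
}

gcad_block_fwd <- function(w, x) {
  xa <- fwd_ln(w$norm1, x)
  xs1 <- ag_add(xa, fwd_ln(w$norm2, mca_fwd(w, xa)))
  mlp <- fwd_conv(w$mlp_out, ag_gelu(fwd_conv(w$mlp_in, xs1, pad = 0L)), pad = 0L)
  ag_add(xs1, mlp)
}

decoder_init <- function(channels, use_gcad = TRUE, mlp_ratio = 4L) {
  # channels: the encoder ladder c(C1, 2C1, 4C1, 8C1, 16C1)
  stages <- vector("list", 4L)
  for (s in 4:1) {
    stages[[s]] <- list(
      up = nn_convT(channels[s + 1], channels[s]),
      fuse = nn_conv(1L, 2L * channels[s], channels[s]),
      gcad = if (use_gcad) gcad_init(channels[s], mlp_ratio)
    )
  }
  c_half <- max(channels[1] %/% 2L, 8L)
  list(stages = stages, use_gcad = use_gcad,
       final_up = nn_convT(channels[1], c_half),
       head = nn_conv(1L, c_half, 1L))
}

decoder_fwd <- function(dec, msee_w, skips, bottleneck, training = TRUE) {
  z <- bottleneck
  for (s in 4:1) {
    st <- dec$stages[[s]]
    z <- ag_convT2x2(z, st$up$w, st$up$b)
    skip <- msee_fwd(msee_w[[s]], skips[[s]], training = training)
    z <- fwd_conv(st$fuse, ag_concat_ch(list(z, skip)), pad = 0L)
    if (dec$use_gcad) z <- gcad_block_fwd(st$gcad, z)
  }
  z <- ag_gelu(ag_convT2x2(z, dec$final_up$w, dec$final_up$b))
  fwd_conv(dec$head, z, pad = 0L)
}

## ---- exported array-level surface ----

#' Multi-scale context aggregation forward pass
#'
#' `F1 = DWC6(XA); F2 = DWC4(XA+F1); F3 = DWC2(XA+F2); F4 = AvgPool(XA);
#' Xcon = concat(XA, F2, F3, F1+F4)` followed by a multiplicative SiLU gate
#' and a 1x1 fusion convolution.
#'
#' @param weights a decoder-block weight list (one `model$decoder$stages[[s]]$gcad`).
#' @param x numeric array `(H, W, C)`.
#' @return numeric array `(H, W, C)`.
#' @export
mca_forward <- function(weights, x) {
  check_finite(x, "mca input")
  with_no_grad(mca_fwd(weights, ag_const(x))$v)
}

#' Decoder block forward pass (pre-norm residual around MCA, plus MLP)
#'
#' @inheritParams mca_forward
#' @return numeric array `(H, W, C)`.
#' @export
gcad_block <- function(weights, x) {
  check_finite(x, "gcad input")
  with_no_grad(gcad_block_fwd(weights, ag_const(x))$v)
}

#' Decode the feature pyramid into a full-resolution logits map
#'
#' Starting from the attention-refined bottleneck, each stage upsamples 2x
#' (transposed convolution with channel halving), concatenates the
#' edge-enhanced skip, fuses with a 1x1 convolution and applies the decoder
#' block; a final 2x expansion and 1x1 head produce single-channel logits.
#'
#' @param model model object from [build_model()].
#' @param pyramid list of five encoder feature maps (see [encode()]).
#' @param bottleneck bottleneck feature map `(S/32, S/32, C5)`; defaults to
#'   the attention-refined deepest pyramid level.
#' @return numeric array `(S, S, 1)` of logits.
#' @export
decode <- function(model, pyramid, bottleneck = NULL) {
  ch <- model$encoder$channels
  for (s in 1:5) {
    if (dim(pyramid[[s]])[3] != ch[s])
      err_validation("pyramid/decoder channel mismatch")
  }
  with_no_grad({
    bn <- if (is.null(bottleneck)) {
      parm_fwd(model$parm, ag_const(pyramid[[5]]))
    } else {
      if (!all(dim(bottleneck) == dim(pyramid[[5]])))
        err_validation("bottleneck/pyramid shape mismatch")
      ag_const(bottleneck)
    }
    skips <- lapply(pyramid[1:4], ag_const)
    decoder_fwd(model$decoder, model$msee, skips, bn, training = FALSE)$v
  })
}
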