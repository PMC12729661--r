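# Pyramid-attention bottleneck.
#
# Stage 1 pools the bottleneck map to several grids (1x1, 3x3, 5x5, 7x7 by
# default), upsamples each back bilinearly and concatenates with the input.
# Stage 2 runs channel-compressed, grouped non-local attention: queries and
# keys come from the pooled stack, values from the raw input; each query
# position attends over all spatial positions (softmax over key positions);
# a 1x1 convolution restores the channel width and the input is added back.

parm_init <- function(ch, pool_sizes = c(1L, 3L, 5L, 7L),
                      cprime = NULL, groups = 4L) {
  if (is.null(cprime)) cprime <- max(groups, ch %/% 4L)
  stopifnot(cprime < ch, cprime %% groups == 0L)
  k <- length(pool_sizes) + 1L
  list(
    pool_sizes = as.integer(pool_sizes),
    phi = nn_conv(1L, k * ch, cprime),
    theta = nn_conv(1L, k * ch, cprime),
    g = nn_conv(1L, ch, cprime),
    out = nn_conv(1L, cprime, ch),
    cprime = cprime, groups = groups, ch = ch
  )
}

ppool_fwd <- function(w, x) {
  d <- dim(x$v)
  if (length(w$pool_sizes) == 0L) return(x)
  if (d[1] < max(w$pool_sizes) || d[2] < max(w$pool_sizes))
    err_validation("feature map smaller than the largest pooling grid")
  branches <- lapply(w$pool_sizes, function(g) {
    ag_upsample_bilinear(ag_adaptive_avgpool(x, g, g), d[1], d[2])
  })
  ag_concat_ch(c(branches, list(x)))
}

parm_fwd <- function(w, x) {
  d <- dim(x$v); hw <- d[1] * d[2]
  pm <- ppool_fwd(w, x)
  q <- ag_t(ag_reshape(fwd_conv(w$phi, pm, pad = 0L), c(hw, w$cprime)))   # C' x HW
  k <- ag_t(ag_reshape(fwd_conv(w$theta, pm, pad = 0L), c(hw, w$cprime)))
  v <- ag_t(ag_reshape(fwd_conv(w$g, x, pad = 0L), c(hw, w$cprime)))
  cg <- w$cprime %/% w$groups
  outs <- vector("list", w$groups)
  for (gi in seq_len(w$groups)) {
    rows <- (gi - 1L) * cg + seq_len(cg)
    qg <- ag_slice_rows(q, rows); kg <- ag_slice_rows(k, rows)
    vg <- ag_slice_rows(v, rows)
    s <- ag_softmax_rows(ag_matmul(ag_t(qg), kg))        # HW x HW
    outs[[gi]] <- ag_matmul(vg, ag_t(s))                 # cg x HW
  }
  agg <- if (w$groups == 1L) outs[[1]] else {
    acc <- outs[[1]]
    for (gi in 2:w$groups) acc <- ag_rbind(acc, outs[[gi]])
    acc
  }
  gamma <- ag_reshape(ag_t(agg), c(d[1], d[2], w$cprime))
  ag_add(fwd_conv(w$out, gamma, pad = 0L), x)
}

## ---- exported array-level surface ----

#' Pyramid pooling and concatenation
#'
#' Adaptive average pooling to each configured grid, bilinear upsampling
#' back to the input resolution, and channel concatenation with the input.
#'
#' @param weights a PARM weight list (`model$parm`).
#' @param x numeric array `(H, W, C)`.
#' @return numeric array `(H, W, (k+1) C)` for `k` pooling branches.
#' @export
pyramid_pool_concat <- function(weights, x) {
  with_no_grad(ppool_fwd(weights, ag_const(x))$v)
}

#' Pyramid-attention bottleneck forward pass
#'
#' @inheritParams pyramid_pool_concat
#' @return numeric array `(H, W, C)` (shape preserved; residual output).
#' @export
parm_forward <- function(weights, x) {
  check_finite(x, "parm input")
  with_no_grad(parm_fwd(weights, ag_const(x))$v)
}
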