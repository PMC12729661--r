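# Five-stage state-space encoder.
#
# Stage 1 is a 7x7, stride-2 convolutional stem with 2-D instance
# normalization; stages 2-5 downsample with a 2x2 patch embedding / patch
# merging convolution and then apply visual state-space (VSS) blocks whose
# sequence core is a four-direction selective scan (SS2D). Channels double
# every stage (48 -> 96 -> 192 -> 384 -> 768 at the default width), spatial
# dims halve (S/2 ... S/32). No positional embeddings are used anywhere: the
# scan order itself carries position.

SS2D_STATE <- 16L
SS2D_EXPAND <- 2L

# the four flattening orders of an H x W grid: column-major fwd/bwd
# (h fastest) and row-major fwd/bwd (w fastest); native array order is
# column-major
scan_orders <- function(H, W) {
  L <- H * W
  rowmajor <- as.vector(t(matrix(seq_len(L), H, W)))
  list(seq_len(L), rev(seq_len(L)), rowmajor, rev(rowmajor))
}

ss2d_init <- function(d, d_state = SS2D_STATE) {
  R <- max(1L, as.integer(ceiling(d / 16)))
  dirs <- lapply(1:4, function(k) {
    # dt bias initialized so softplus(dt_bias) spans ~[1e-3, 1e-1]
    dt0 <- exp(stats::runif(d, log(1e-3), log(1e-1)))
    list(
      x_proj = ag_param(matrix(rinit(d * (R + 2L * d_state), d), R + 2L * d_state, d)),
      dt_w   = ag_param(matrix(rinit(d * R, R), d, R)),
      dt_b   = ag_param(log(expm1(dt0))),
      A_log  = ag_param(matrix(log(rep(seq_len(d_state), each = d)), d, d_state)),
      D      = ag_param(rep(1, d))
    )
  })
  list(dirs = dirs, d = d, N = d_state, R = R)
}

# selective 2-D scan on an (H, W, d) map: four flattening directions, each
# run through the input-dependent state-space recurrence, outputs summed
ss2d_core <- function(w, x) {
  d <- dim(x$v)
  L <- d[1] * d[2]
  u0 <- ag_t(ag_reshape(x, c(L, d[3])))          # d x L, column-major order
  ords <- scan_orders(d[1], d[2])
  out <- NULL
  for (k in 1:4) {
    pk <- w$dirs[[k]]
    idx <- ords[[k]]
    uk <- if (k == 1L) u0 else ag_gather_cols(u0, idx)
    dbl <- ag_matmul(pk$x_proj, uk)              # (R + 2N) x L
    dts <- ag_slice_rows(dbl, seq_len(w$R))
    Bm <- ag_slice_rows(dbl, w$R + seq_len(w$N))
    Cm <- ag_slice_rows(dbl, w$R + w$N + seq_len(w$N))
    delta <- ag_softplus(ag_add_rowvec(ag_matmul(pk$dt_w, dts), pk$dt_b))
    A <- ag_neg(ag_exp(pk$A_log))
    yk <- ag_scan(uk, delta, A, Bm, Cm, pk$D)
    if (k > 1L) yk <- ag_gather_cols(yk, order(idx))
    out <- if (is.null(out)) yk else ag_add(out, yk)
  }
  ag_reshape(ag_t(out), d)
}

vss_init <- function(ch, expand = SS2D_EXPAND, d_state = SS2D_STATE) {
  d <- expand * ch
  list(
    ln = nn_layernorm(ch),
    lin_gate = nn_linear(ch, d),
    lin_in = nn_linear(ch, d),
    dw = nn_dwconv(3L, d),
    ss2d = ss2d_init(d, d_state),
    out_ln = nn_layernorm(d),
    out_proj = nn_linear(d, ch),
    ch = ch
  )
}

vss_fwd <- function(w, x) {
  xa <- fwd_ln(w$ln, x)
  gate <- ag_silu(fwd_linear_ch(w$lin_gate, xa))
  t1 <- ag_silu(fwd_dwconv(w$dw, fwd_linear_ch(w$lin_in, xa)))
  y <- fwd_ln(w$out_ln, ss2d_core(w$ss2d, t1))
  ag_add(x, fwd_linear_ch(w$out_proj, ag_mul(gate, y)))
}

encoder_init <- function(base = 48L, depths = c(2L, 2L, 2L, 2L),
                         d_state = SS2D_STATE, expand = SS2D_EXPAND) {
  ch <- base * c(1L, 2L, 4L, 8L, 16L)
  stages <- vector("list", 4L)
  downs <- vector("list", 4L)
  for (s in 1:4) {
    cin <- if (s == 1L) ch[1] else ch[s]
    downs[[s]] <- list(conv = nn_conv(2L, cin, ch[s + 1], bias = FALSE),
                       ln = nn_layernorm(ch[s + 1]))
    stages[[s]] <- lapply(seq_len(depths[s]),
                          function(i) vss_init(ch[s + 1], expand, d_state))
  }
  list(stem = list(conv = nn_conv(7L, 3L, ch[1]), inorm = nn_instancenorm(ch[1])),
       downs = downs, stages = stages, channels = ch, depths = depths)
}

stem_fwd <- function(stem, x) {
  fwd_in(stem$inorm, fwd_conv(stem$conv, x, stride = 2L, pad = 3L))
}

encoder_fwd <- function(enc, x) {
  lv <- vector("list", 5L)
  z <- stem_fwd(enc$stem, x)
  lv[[1]] <- z
  for (s in 1:4) {
    dn <- enc$downs[[s]]
    z <- fwd_ln(dn$ln, ag_conv2d(z, dn$conv$w, NULL, stride = 2L, pad = 0L))
    for (blk in enc$stages[[s]]) z <- vss_fwd(blk, z)
    lv[[s + 1]] <- z
  }
  lv
}

gray_to_3ch <- function(px) {
  # grayscale replicated to three channels (keeps the stem shape-compatible
  # with RGB-pretrained backbones)
  array(rep(px, 3L), dim = c(nrow(px), ncol(px), 3L))
}

## ---- exported array-level surface ----

#' Convolutional stem: 7x7 stride-2 convolution + instance normalization
#'
#' @param weights stem weights (`model$encoder$stem` from [build_model()]).
#' @param x numeric array `(H, W, 3)`.
#' @return numeric array `(H/2, W/2, C1)`.
#' @export
stem_forward <- function(weights, x) {
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    err_validation("stem expects an (H, W, 3) array")
  with_no_grad(stem_fwd(weights, ag_const(x))$v)
}

#' Four-direction selective 2-D scan
#'
#' Flattens the feature map in four orders (column-major and row-major, each
#' forward and backward), runs the input-dependent state-space recurrence
#' `h_t = exp(delta_t A) h_{t-1} + delta_t B_t x_t`,
#' `y_t = C_t h_t + D x_t` along each sequence, and sums the four outputs.
#'
#' @param weights SS2D weights as produced by the model builder (fields
#'   `dirs`, `d`, `N`, `R`).
#' @param x numeric array `(H, W, d)`.
#' @return numeric array `(H, W, d)`.
#' @export
ss2d_forward <- function(weights, x) {
  check_finite(x, "ss2d input")
  if (dim(x)[3] != weights$d) err_validation("ss2d channel mismatch")
  with_no_grad(ss2d_core(weights, ag_const(x))$v)
}

#' Visual state-space block forward pass
#'
#' Two-branch gated unit: `out = x + Linear(SiLU(Linear(LN x)) *
#' LN(SS2D(SiLU(DWConv(Linear(LN x))))))`.
#'
#' @param weights a VSS block weight list.
#' @param x numeric array `(H, W, C)` with `C` equal to the block width.
#' @return numeric array of the same shape.
#' @export
vss_block_forward <- function(weights, x) {
  check_finite(x, "vss input")
  if (dim(x)[3] != weights$ch) err_validation("vss channel mismatch")
  with_no_grad(vss_fwd(weights, ag_const(x))$v)
}

#' Encode a frame into the five-level feature pyramid
#'
#' @param model model object from [build_model()].
#' @param frame an `ultrasound_frame` (or a plain `(H, W)` matrix in `[0,1]`).
#' @return list of five arrays with shapes
#'   `(S/2, S/2, C1)` ... `(S/32, S/32, 16 C1)`.
#' @export
encode <- function(model, frame) {
  px <- if (inherits(frame, "ultrasound_frame")) frame$pixels else frame
  if (nrow(px) %% 32L != 0L || ncol(px) %% 32L != 0L)
    err_validation("input size must be divisible by 32")
  with_no_grad(lapply(encoder_fwd(model$encoder, ag_const(gray_to_3ch(px))),
                      function(n) n$v))
}
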