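# Trainable-layer constructors. Each returns a plain list of ag_param nodes
# (plus fixed metadata); `collect_params()` walks any nested structure and
# gathers every parameter node for the optimizer.
#
# Initialization follows the usual fan-in uniform rule U(-s, s) with
# s = sqrt(1 / fan_in); builders are called under a fixed seed by the model
# constructor, so weight initialization is fully reproducible.

rinit <- function(n, fan_in) stats::runif(n, -1, 1) * sqrt(1 / max(fan_in, 1))

nn_linear <- function(cin, cout, bias = TRUE, zero = FALSE) {
  w <- if (zero) matrix(0, cin, cout) else matrix(rinit(cin * cout, cin), cin, cout)
  l <- list(w = ag_param(w))
  if (bias) l$b <- ag_param(if (zero) numeric(cout) else rinit(cout, cin))
  l
}

nn_conv <- function(k, cin, cout, bias = TRUE, zero = FALSE) {
  fan <- k * k * cin
  w <- array(if (zero) 0 else rinit(k * k * cin * cout, fan), dim = c(k, k, cin, cout))
  l <- list(w = ag_param(w), k = k)
  if (bias) l$b <- ag_param(if (zero) numeric(cout) else rinit(cout, fan))
  l
}

nn_dwconv <- function(k, ch, bias = TRUE) {
  l <- list(w = ag_param(array(rinit(k * k * ch, k * k), dim = c(k, k, ch))), k = k)
  if (bias) l$b <- ag_param(rinit(ch, k * k))
  l
}

# depthwise-separable convolution: k x k depthwise followed by a 1 x 1
# pointwise projection (the "DConv" building block of the skip and decoder
# modules)
nn_dsconv <- function(k, cin, cout, bias = TRUE, zero = FALSE) {
  list(dw = nn_dwconv(k, cin, bias = FALSE), pw = nn_conv(1, cin, cout, bias = bias, zero = zero), k = k)
}

nn_convT <- function(cin, cout) {
  # weight laid out as the adjoint convolution (2, 2, cout, cin)
  fan <- 4 * cin
  list(w = ag_param(array(rinit(4 * cout * cin, fan), dim = c(2, 2, cout, cin))),
       b = ag_param(rinit(cout, fan)))
}

nn_layernorm <- function(ch) list(g = ag_param(rep(1, ch)), b = ag_param(numeric(ch)))

nn_instancenorm <- function(ch) list(g = ag_param(rep(1, ch)), b = ag_param(numeric(ch)))

nn_batchnorm <- function(ch, momentum = 0.1) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(ch); st$var <- rep(1, ch)
  list(g = ag_param(rep(1, ch)), b = ag_param(numeric(ch)),
       state = st, momentum = momentum)
}

## forward helpers -----------------------------------------------------------

fwd_linear_ch <- function(l, x) ag_linear_ch(x, l$w, l$b)

fwd_conv <- function(l, x, stride = 1L, pad = NULL, dil = 1L) {
  if (is.null(pad)) pad <- as.integer(dil * (l$k - 1) / 2)
  ag_conv2d(x, l$w, l$b, stride = stride, pad = pad, dil = dil)
}

fwd_dwconv <- function(l, x, stride = 1L, pad = NULL, dil = 1L) {
  if (is.null(pad)) pad <- as.integer(dil * (l$k - 1) / 2)
  ag_dwconv2d(x, l$w, l$b, stride = stride, pad = pad, dil = dil)
}

fwd_dsconv <- function(l, x, dil = 1L) {
  pad <- as.integer(dil * (l$k - 1) / 2)
  x <- ag_dwconv2d(x, l$dw$w, NULL, stride = 1L, pad = pad, dil = dil)
  ag_conv2d(x, l$pw$w, l$pw$b, stride = 1L, pad = 0L)
}

fwd_ln <- function(l, x) ag_layernorm_ch(x, l$g, l$b)

fwd_in <- function(l, x) ag_instancenorm(x, l$g, l$b)

# batch norm over one image: spatial statistics per channel during training
# (batch of one), running statistics at inference
fwd_bn <- function(l, x, training = TRUE, eps = 1e-5) {
  if (training) {
    d <- dim(x$v); hw <- d[1] * d[2]
    m <- matrix(x$v, hw, d[3])
    mu <- colMeans(m); va <- colMeans(sweep(m, 2, mu)^2)
    st <- l$state; mom <- l$momentum
    st$mean <- (1 - mom) * st$mean + mom * mu
    st$var <- (1 - mom) * st$var + mom * va * hw / max(hw - 1, 1)
    fwd_in(l, x)
  } else {
    st <- l$state
    d <- dim(x$v); hw <- d[1] * d[2]
    scale <- l$g$v / sqrt(st$var + eps)
    shift <- l$b$v - st$mean * scale
    sc <- ag_const(array(rep(scale, each = hw), dim = d))
    sh <- ag_const(array(rep(shift, each = hw), dim = d))
    ag_add(ag_mul(x, sc), sh)
  }
}

## parameter bookkeeping -----------------------------------------------------

collect_params <- function(x) {
  out <- list()
  walk <- function(e) {
    if (is_ag(e)) {
      if (e$req) out[[length(out) + 1L]] <<- e
    } else if (is.list(e)) {
      for (el in e) walk(el)
    }
  }
  walk(x)
  out
}

#' Number of trainable parameters in a model
#'
#' @param model a model object as returned by [build_model()] (or any nested
#'   list of layers).
#' @return integer scalar, total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_params(model), function(p) length(p$v), numeric(1)))
}

## AdamW ---------------------------------------------------------------------

adamw_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 5e-2) {
  list(params = params, lr = lr, b1 = beta1, b2 = beta2, eps = eps,
       wd = weight_decay, t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p$v) %||% length(p$v))),
       v = lapply(params, function(p) array(0, dim = dim(p$v) %||% length(p$v))))
}

adamw_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t; bc2 <- 1 - opt$b2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * g
    opt$v[[i]] <- opt$b2 * opt$v[[i]] + (1 - opt$b2) * g * g
    mhat <- opt$m[[i]] / bc1; vhat <- opt$v[[i]] / bc2
    p$v[] <- p$v - opt$lr * (mhat / (sqrt(vhat) + opt$eps) + opt$wd * p$v)
  }
  opt
}

zero_grads <- function(params) for (p in params) p$grad <- NULL
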