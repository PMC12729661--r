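# Reverse-mode automatic differentiation over dense arrays.
#
# Feature maps are numeric arrays with dim = c(H, W, C) (row, column,
# channel; each channel plane contiguous). A node is an environment holding
# the value `v`, a `req` flag (TRUE if any ancestor is a trainable
# parameter), its `parents` and a backward closure `bk` that maps the
# accumulated output gradient to per-parent gradients. When gradients are
# globally disabled (inference) every op returns a constant node, so no
# graph is retained.

.ag <- new.env(parent = emptyenv())
.ag$grad_on <- TRUE
.ag$id <- 0L

ag_grad_enabled <- function(on) {
  old <- .ag$grad_on
  .ag$grad_on <- on
  invisible(old)
}

with_no_grad <- function(expr) {
  old <- ag_grad_enabled(FALSE)
  on.exit(ag_grad_enabled(old))
  expr
}

ag_tensor <- function(v, req = FALSE, parents = NULL, bk = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$req <- req
  n$parents <- parents
  n$bk <- bk
  n$grad <- NULL
  .ag$id <- .ag$id + 1L
  n$id <- .ag$id
  class(n) <- "ag"
  n
}

ag_param <- function(v, name = NULL) {
  n <- ag_tensor(v, req = TRUE)
  n$name <- name
  n
}

ag_const <- function(v) ag_tensor(v)

is_ag <- function(x) inherits(x, "ag")

as_ag <- function(x) if (is_ag(x)) x else ag_const(x)

# Generic op constructor: computes `value`, and unless gradients are off (or
# no parent needs them) records parents + backward closure.
ag_op <- function(value, parents, bk) {
  req <- .ag$grad_on && any(vapply(parents, function(p) p$req, logical(1)))
  if (!req) return(ag_tensor(value))
  ag_tensor(value, req = TRUE, parents = parents, bk = bk)
}

# Backpropagate from a scalar loss node; afterwards every parameter node
# reachable from `loss` carries its gradient in $grad.
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$v) == 1L)
  # iterative DFS topological sort
  order <- vector("list", 256L); norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L)); nstack <- 1L
  while (nstack > 0L) {
    fr <- stack[[nstack]]
    node <- fr$node
    if (fr$stage == 1L) {
      stack[[nstack]]$stage <- 2L
      key <- as.character(node$id)
      if (!is.null(seen[[key]])) { nstack <- nstack - 1L; next }
      seen[[key]] <- TRUE
      for (p in node$parents) if (p$req && !is.null(p$bk) || p$req) {
        if (is.null(seen[[as.character(p$id)]])) {
          nstack <- nstack + 1L
          stack[[nstack]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
      nstack <- nstack - 1L
    }
  }
  for (i in seq_len(norder)) order[[i]]$grad <- NULL
  loss$grad <- array(1, dim = dim(loss$v) %||% 1L)
  for (i in rev(seq_len(norder))) {
    node <- order[[i]]
    if (is.null(node$bk) || is.null(node$grad)) next
    gs <- node$bk(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$req) next
      g <- gs[[j]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!is.null(node$parents)) node$grad <- NULL  # free intermediate grads
  }
  invisible(loss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

keepdim <- function(g, d) { dim(g) <- d; g }

## ---- elementwise arithmetic ----

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$v + b$v, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$v - b$v, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$v; bv <- b$v
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, s) {  # s plain scalar
  ag_op(a$v * s, list(a), function(g) list(g * s))
}

# multiply by a scalar parameter (e.g. attention temperature)
ag_scale_p <- function(a, s) {
  av <- a$v; sv <- as.numeric(s$v)
  ag_op(av * sv, list(a, s), function(g) list(g * sv, sum(g * av)))
}

ag_add_bias <- function(x, b) {  # x (H,W,C), b length C
  d <- dim(x$v); hw <- d[1] * d[2]
  ag_op(x$v + rep(b$v, each = hw), list(x, b), function(g) {
    list(g, colSums(matrix(g, hw, d[3])))
  })
}

ag_sum <- function(x) ag_op(sum(x$v), list(x), function(g) {
  list(array(as.numeric(g), dim = dim(x$v) %||% length(x$v)))
})

ag_mean <- function(x) {
  n <- length(x$v)
  ag_op(sum(x$v) / n, list(x), function(g) {
    list(array(as.numeric(g) / n, dim = dim(x$v) %||% n))
  })
}

## ---- activations ----

ag_relu <- function(x) {
  m <- x$v > 0
  ag_op(x$v * m, list(x), function(g) list(g * m))
}

ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  ag_op(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_silu <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  ag_op(x$v * s, list(x), function(g) list(g * (s + x$v * s * (1 - s))))
}

ag_gelu <- function(x) {
  ph <- stats::pnorm(x$v)
  ag_op(x$v * ph, list(x), function(g) list(g * (ph + x$v * stats::dnorm(x$v))))
}

ag_softplus <- function(x) {
  v <- ifelse(x$v > 30, x$v, log1p(exp(pmin(x$v, 30))))
  s <- 1 / (1 + exp(-x$v))
  ag_op(v, list(x), function(g) list(g * s))
}

ag_log <- function(x) ag_op(log(x$v), list(x), function(g) list(g / x$v))

ag_clip <- function(x, lo, hi) {
  m <- x$v >= lo & x$v <= hi
  ag_op(pmin(pmax(x$v, lo), hi), list(x), function(g) list(g * m))
}

# exact square root with a guarded backward (derivative clamped near zero,
# so gradient stays finite at exactly-zero inputs e.g. constant images)
ag_sqrt_guard <- function(x, guard = 1e-6) {
  v <- sqrt(x$v)
  ag_op(v, list(x), function(g) list(g * 0.5 / pmax(v, guard)))
}

## ---- shape ops ----

ag_reshape <- function(x, d) {
  od <- dim(x$v) %||% length(x$v)
  v <- x$v; dim(v) <- d
  ag_op(v, list(x), function(g) { dim(g) <- od; list(g) })
}

ag_concat_ch <- function(xs) {  # list of (H,W,Ci) -> (H,W,sum Ci)
  vs <- lapply(xs, function(x) x$v)
  d1 <- dim(vs[[1]])
  cs <- vapply(vs, function(v) dim(v)[3], numeric(1))
  out <- array(unlist(vs, use.names = FALSE), dim = c(d1[1], d1[2], sum(cs)))
  ag_op(out, xs, function(g) {
    res <- vector("list", length(xs)); off <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- g[, , off + seq_len(cs[i]), drop = FALSE]
      off <- off + cs[i]
    }
    res
  })
}

ag_slice_ch <- function(x, idx) {
  d <- dim(x$v)
  ag_op(x$v[, , idx, drop = FALSE], list(x), function(g) {
    gx <- array(0, dim = d); gx[, , idx] <- g; list(gx)
  })
}

## ---- linear algebra ----

ag_matmul <- function(a, b) {
  av <- a$v; bv <- b$v
  ag_op(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

# per-pixel linear map over channels: x (H,W,C) -> (H,W,Cout), w (C,Cout)
ag_linear_ch <- function(x, w, b = NULL) {
  d <- dim(x$v); hw <- d[1] * d[2]
  xm <- matrix(x$v, hw, d[3])
  wv <- w$v
  ym <- xm %*% wv
  if (!is.null(b)) {
    y <- array(ym, dim = c(d[1], d[2], ncol(wv))) # bias added below
    node <- ag_op(y + rep(b$v, each = hw), list(x, w, b), function(g) {
      gm <- matrix(g, hw, ncol(wv))
      list(keepdim(gm %*% t(wv), d), crossprod(xm, gm), colSums(gm))
    })
  } else {
    node <- ag_op(array(ym, dim = c(d[1], d[2], ncol(wv))), list(x, w),
                  function(g) {
      gm <- matrix(g, hw, ncol(wv))
      list(keepdim(gm %*% t(wv), d), crossprod(xm, gm))
    })
  }
  node
}

# softmax over the last axis of a matrix (each row sums to one), with
# numerical max-shift.
ag_softmax_rows <- function(x) {
  v <- x$v
  m <- v - apply(v, 1, max)
  e <- exp(m)
  s <- e / rowSums(e)
  ag_op(s, list(x), function(g) {
    list((g - rowSums(g * s)) * s)
  })
}

## ---- convolution / pooling / resampling ----

ag_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  xv <- x$v; wv <- w$v
  y <- .cpp_conv_fwd(xv, wv, stride, pad, dil)
  d <- dim(xv)
  parents <- list(x, w); hw <- dim(y)[1] * dim(y)[2]
  if (!is.null(b)) {
    y <- y + rep(b$v, each = hw)
    parents <- c(parents, list(b))
  }
  ag_op(y, parents, function(g) {
    gr <- .cpp_conv_bwd(xv, wv, g, stride, pad, dil)
    out <- list(gr$gx, gr$gw)
    if (length(parents) == 3L) out <- c(out, list(colSums(matrix(g, hw))))
    out
  })
}

ag_dwconv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  xv <- x$v; wv <- w$v
  y <- .cpp_dwconv_fwd(xv, wv, stride, pad, dil)
  d <- dim(xv)
  parents <- list(x, w); hw <- dim(y)[1] * dim(y)[2]
  if (!is.null(b)) {
    y <- y + rep(b$v, each = hw)
    parents <- c(parents, list(b))
  }
  ag_op(y, parents, function(g) {
    gx <- .cpp_dwconv_bwd_input(g, wv, d[1], d[2], stride, pad, dil)
    gw <- .cpp_dwconv_bwd_weight(xv, g, dim(wv)[1], dim(wv)[2], stride, pad, dil)
    out <- list(gx, gw)
    if (length(parents) == 3L) out <- c(out, list(colSums(matrix(g, hw))))
    out
  })
}

# 2x2, stride-2 transposed convolution; weight dim (2, 2, Cout, Cin).
ag_convT2x2 <- function(x, w, b = NULL) {
  xv <- x$v; wv <- w$v
  d <- dim(xv)
  y <- .cpp_conv_bwd_input(xv, wv, 2L * d[1], 2L * d[2], 2L, 0L, 1L)
  parents <- list(x, w); hw <- dim(y)[1] * dim(y)[2]
  if (!is.null(b)) {
    y <- y + rep(b$v, each = hw)
    parents <- c(parents, list(b))
  }
  ag_op(y, parents, function(g) {
    gx <- .cpp_conv_fwd(g, wv, 2L, 0L, 1L)
    gw <- .cpp_conv_bwd_weight(g, xv, 2L, 2L, 2L, 0L, 1L)
    out <- list(gx, gw)
    if (length(parents) == 3L) out <- c(out, list(colSums(matrix(g, hw))))
    out
  })
}

ag_pad_replicate <- function(x, p) {
  d <- dim(x$v)
  ri <- pmin(pmax(seq_len(d[1] + 2 * p) - p, 1L), d[1])
  ci <- pmin(pmax(seq_len(d[2] + 2 * p) - p, 1L), d[2])
  ag_op(x$v[ri, ci, , drop = FALSE], list(x), function(g) {
    # scatter-add via rowsum on both spatial axes
    gm <- rowsum(matrix(g, length(ri)), ri)          # (H, (W+2p)*C)
    ga <- array(gm, dim = c(d[1], length(ci), d[3]))
    ga <- aperm(ga, c(2, 1, 3))
    gm2 <- rowsum(matrix(ga, length(ci)), ci)
    list(aperm(array(gm2, dim = c(d[2], d[1], d[3])), c(2, 1, 3)))
  })
}

# adaptive average pooling to a gh x gw grid (inclusive fractional bins as
# in the usual adaptive-pool convention)
ag_adaptive_avgpool <- function(x, gh, gw) {
  d <- dim(x$v)
  hb <- cbind(floor((seq_len(gh) - 1) * d[1] / gh) + 1,
              ceiling(seq_len(gh) * d[1] / gh))
  wb <- cbind(floor((seq_len(gw) - 1) * d[2] / gw) + 1,
              ceiling(seq_len(gw) * d[2] / gw))
  out <- array(0, dim = c(gh, gw, d[3]))
  for (i in seq_len(gh)) for (j in seq_len(gw)) {
    blk <- x$v[hb[i, 1]:hb[i, 2], wb[j, 1]:wb[j, 2], , drop = FALSE]
    out[i, j, ] <- colMeans(matrix(blk, ncol = d[3]))
  }
  ag_op(out, list(x), function(g) {
    gx <- array(0, dim = d)
    for (i in seq_len(gh)) for (j in seq_len(gw)) {
      rs <- hb[i, 1]:hb[i, 2]; cs <- wb[j, 1]:wb[j, 2]
      nij <- length(rs) * length(cs)
      gx[rs, cs, ] <- gx[rs, cs, ] +
        rep(g[i, j, ] / nij, each = nij)
    }
    list(gx)
  })
}

# Interpolation matrix for 1-D bilinear resize n -> m (align_corners = FALSE)
bilinear_matrix <- function(n, m) {
  M <- matrix(0, m, n)
  for (i in seq_len(m)) {
    src <- (i - 0.5) * n / m - 0.5
    lo <- floor(src); fr <- src - lo
    lo1 <- min(max(lo + 1, 1), n); hi1 <- min(max(lo + 2, 1), n)
    M[i, lo1] <- M[i, lo1] + (1 - fr)
    M[i, hi1] <- M[i, hi1] + fr
  }
  M
}

ag_upsample_bilinear <- function(x, H2, W2) {
  d <- dim(x$v)
  Rm <- bilinear_matrix(d[1], H2); Cm <- bilinear_matrix(d[2], W2)
  v <- x$v
  out <- array(0, dim = c(H2, W2, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- Rm %*% v[, , c] %*% t(Cm)
  ag_op(out, list(x), function(g) {
    gx <- array(0, dim = d)
    for (c in seq_len(d[3])) gx[, , c] <- t(Rm) %*% g[, , c] %*% Cm
    list(gx)
  })
}

## ---- normalizations ----

# layer normalization over the channel axis at every pixel
ag_layernorm_ch <- function(x, gamma, beta, eps = 1e-6) {
  d <- dim(x$v); hw <- d[1] * d[2]; C <- d[3]
  m <- matrix(x$v, hw, C)
  mu <- rowMeans(m)
  xc <- m - mu
  va <- rowMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * istd
  y <- sweep(xhat, 2, gamma$v, `*`)
  y <- sweep(y, 2, beta$v, `+`)
  ag_op(keepdim(y, d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, hw, C)
    dxh <- sweep(gm, 2, gamma$v, `*`)
    dx <- istd * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
    list(keepdim(dx, d), colSums(gm * xhat), colSums(gm))
  })
}

# instance normalization: each channel normalized over its spatial plane
ag_instancenorm <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x$v); hw <- d[1] * d[2]; C <- d[3]
  m <- matrix(x$v, hw, C)
  mu <- colMeans(m)
  xc <- sweep(m, 2, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, gamma$v, `*`), 2, beta$v, `+`)
  ag_op(keepdim(y, d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, hw, C)
    dxh <- sweep(gm, 2, gamma$v, `*`)
    dx <- sweep(dxh - rep(colMeans(dxh), each = hw) -
                xhat * rep(colMeans(dxh * xhat), each = hw), 2, istd, `*`)
    list(keepdim(dx, d), colSums(gm * xhat), colSums(gm))
  })
}

## ---- selective scan ----

# One scan direction: u, delta (d x L); A (d x N); B, Cc (N x L); D (d).
ag_scan <- function(u, delta, A, B, Cc, D) {
  res <- .cpp_scan_fwd(u$v, delta$v, A$v, B$v, Cc$v, D$v)
  hist <- res$h
  uv <- u$v; dv <- delta$v; Av <- A$v; Bv <- B$v; Cv <- Cc$v; Dv <- D$v
  ag_op(res$y, list(u, delta, A, B, Cc, D), function(g) {
    gr <- .cpp_scan_bwd(uv, dv, Av, Bv, Cv, Dv, hist, g)
    list(gr$gu, gr$gdelta, gr$gA, gr$gB, gr$gC, as.numeric(gr$gD))
  })
}

# gather columns of a d x L matrix (scan-direction reordering)
ag_gather_cols <- function(x, idx) {
  d <- dim(x$v)
  ag_op(x$v[, idx, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2]); gx[, idx] <- g; list(gx)
  })
}

## ---- matrix helpers for attention / scan plumbing ----

ag_t <- function(x) ag_op(t(x$v), list(x), function(g) list(t(g)))

ag_slice_rows <- function(x, idx) {
  d <- dim(x$v)
  ag_op(x$v[idx, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2]); gx[idx, ] <- g; list(gx)
  })
}

# add a length-nrow vector to every column of a matrix
ag_add_rowvec <- function(x, v) {
  nc <- ncol(x$v)
  ag_op(x$v + v$v, list(x, v), function(g) list(g, rowSums(g)))
}

ag_exp <- function(x) {
  e <- exp(x$v)
  ag_op(e, list(x), function(g) list(g * e))
}

ag_neg <- function(x) ag_op(-x$v, list(x), function(g) list(-g))

ag_rbind <- function(a, b) {
  na <- nrow(a$v)
  ag_op(rbind(a$v, b$v), list(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}
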