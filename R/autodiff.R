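# Minimal reverse-mode automatic differentiation over numeric arrays.
#
# Nodes are environments carrying $value, an accumulated $grad, and (while a
# tape is recording) a $backward closure that pushes the node's gradient
# into its parents. ad_backward() walks the tape in reverse creation order.
# Gradients are retained on every node, which is what Grad-CAM needs to read
# the gradient at an intermediate activation. The engine is deliberately
# small: only the operations the network uses, each verified against central
# finite differences in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_begin <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  .ad$tape <- t
  invisible(t)
}

ad_end <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

ad_recording <- function() !is.null(.ad$tape)

ad_push <- function(nd) {
  t <- .ad$tape
  n <- t$n + 1L
  if (n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
  t$nodes[[n]] <- nd
  t$n <- n
  nd
}

# Wrap a value as a leaf (parameter or input).
ad_leaf <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd
}

ad_val <- function(x) if (is.environment(x)) x$value else x

ad_node <- function(value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (ad_recording() && !is.null(backward)) {
    nd$backward <- backward
    ad_push(nd)
  }
  nd
}

ad_accum <- function(nd, g) {
  if (!is.environment(nd)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Run backward from a scalar node.
ad_backward <- function(node, seed_grad = 1) {
  stopifnot(ad_recording())
  node$grad <- seed_grad
  t <- .ad$tape
  for (i in seq.int(t$n, 1L)) {
    nd <- t$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# ---- elementwise / linear ops -------------------------------------------

ad_add <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(va + vb, function(g) { ad_accum(a, g); ad_accum(b, g) })
}

ad_sub <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(va - vb, function(g) { ad_accum(a, g); ad_accum(b, -g) })
}

ad_mul <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(va * vb, function(g) { ad_accum(a, g * vb); ad_accum(b, g * va) })
}

ad_smul <- function(a, s) {  # s: plain scalar
  va <- ad_val(a)
  ad_node(va * s, function(g) ad_accum(a, g * s))
}

ad_matmul <- function(a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(va %*% vb, function(g) {
    ad_accum(a, g %*% t(vb))
    ad_accum(b, t(va) %*% g)
  })
}

ad_transpose <- function(a) {
  va <- ad_val(a)
  ad_node(t(va), function(g) ad_accum(a, t(g)))
}

# add a length-ncol row vector to every row of a matrix
ad_addvec <- function(mat, vec) {
  vm <- ad_val(mat); vv <- ad_val(vec)
  ad_node(sweep(vm, 2, vv, "+"), function(g) {
    ad_accum(mat, g)
    ad_accum(vec, colSums(g))
  })
}

ad_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-ad_val(a)))
  ad_node(y, function(g) ad_accum(a, g * y * (1 - y)))
}

ad_tanh <- function(a) {
  y <- tanh(ad_val(a))
  ad_node(y, function(g) ad_accum(a, g * (1 - y^2)))
}

ad_relu <- function(a) {
  va <- ad_val(a)
  y <- pmax(va, 0)
  if (!is.null(dim(va))) dim(y) <- dim(va)
  ad_node(y, function(g) ad_accum(a, g * (va > 0)))
}

ad_sum <- function(a) {
  va <- ad_val(a)
  ad_node(sum(va), function(g) {
    gg <- array(g, if (is.null(dim(va))) length(va) else dim(va))
    ad_accum(a, gg)
  })
}

ad_softmax_rows <- function(a) {
  va <- ad_val(a)
  m <- va - apply(va, 1, max)
  e <- exp(m)
  y <- e / rowSums(e)
  ad_node(y, function(g) {
    ad_accum(a, (g - rowSums(g * y)) * y)
  })
}

ad_concat_cols <- function(lst) {
  vals <- lapply(lst, ad_val)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(do.call(cbind, vals), function(g) {
    for (i in seq_along(lst)) {
      ad_accum(lst[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_cols <- function(a, idx) {
  va <- ad_val(a)
  ad_node(va[, idx, drop = FALSE], function(g) {
    gg <- matrix(0, nrow(va), ncol(va))
    gg[, idx] <- g
    ad_accum(a, gg)
  })
}

ad_rbind <- function(lst) {  # stack 1 x d row matrices into T x d
  vals <- lapply(lst, ad_val)
  ad_node(do.call(rbind, vals), function(g) {
    for (i in seq_along(lst)) {
      ad_accum(lst[[i]], g[i, , drop = FALSE])
    }
  })
}

ad_row <- function(a, i) {
  va <- ad_val(a)
  ad_node(va[i, , drop = FALSE], function(g) {
    gg <- matrix(0, nrow(va), ncol(va))
    gg[i, ] <- g
    ad_accum(a, gg)
  })
}

# mean cross-entropy of rows of logits against integer labels in 1..K
ad_cross_entropy <- function(logits, labels) {
  vl <- ad_val(logits)
  m <- vl - apply(vl, 1, max)
  e <- exp(m)
  p <- e / rowSums(e)
  n <- nrow(vl)
  picked <- p[cbind(seq_len(n), labels)]
  ad_node(-mean(log(pmax(picked, 1e-12))), function(g) {
    onehot <- matrix(0, n, ncol(vl))
    onehot[cbind(seq_len(n), labels)] <- 1
    ad_accum(logits, g * (p - onehot) / n)
  })
}

ad_dropout <- function(a, p, training) {
  va <- ad_val(a)
  if (!training || p <= 0) return(ad_node(va, function(g) ad_accum(a, g)))
  keep <- array(stats::runif(length(va)) >= p, dim(va))
  scale <- 1 / (1 - p)
  ad_node(va * keep * scale, function(g) ad_accum(a, g * keep * scale))
}

# per-row layer normalisation with affine (gamma, beta row vectors)
ad_layernorm_rows <- function(a, gamma, beta, eps = 1e-5) {
  va <- ad_val(a); vg <- ad_val(gamma); vb <- ad_val(beta)
  mu <- rowMeans(va)
  xc <- va - mu
  v <- rowMeans(xc^2)
  sd <- sqrt(v + eps)
  xhat <- xc / sd
  y <- sweep(sweep(xhat, 2, vg, "*"), 2, vb, "+")
  ad_node(y, function(g) {
    d <- ncol(va)
    gghat <- sweep(g, 2, vg, "*")
    ad_accum(gamma, colSums(g * xhat))
    ad_accum(beta, colSums(g))
    term1 <- gghat
    term2 <- rowMeans(gghat)
    term3 <- xhat * rowMeans(gghat * xhat)
    ad_accum(a, (term1 - term2 - term3) / sd)
  })
}

# ---- convolutional ops (H x W x C arrays) -------------------------------

# same-padded depthwise 2-D convolution; w is k x k x C
ad_conv_dw <- function(x, w) {
  vx <- ad_val(x); vw <- ad_val(w)
  d <- dim(vx); k <- dim(vw)[1]; h <- (k - 1) %/% 2
  y <- array(0, d)
  for (c in seq_len(d[3])) {
    xc <- vx[, , c]
    for (m in -h:h) for (n in -h:h) {
      wv <- vw[m + h + 1, n + h + 1, c]
      y[, , c] <- y[, , c] + wv * shift_array(xc, c(-m, -n), fill = 0)
    }
  }
  ad_node(y, function(g) {
    gx <- array(0, d)
    gw <- array(0, dim(vw))
    for (c in seq_len(d[3])) {
      gc <- g[, , c]
      xc <- vx[, , c]
      for (m in -h:h) for (n in -h:h) {
        wv <- vw[m + h + 1, n + h + 1, c]
        gx[, , c] <- gx[, , c] + wv * shift_array(gc, c(m, n), fill = 0)
        gw[m + h + 1, n + h + 1, c] <-
          sum(gc * shift_array(xc, c(-m, -n), fill = 0))
      }
    }
    ad_accum(x, gx)
    ad_accum(w, gw)
  })
}

# pointwise 1x1 convolution: x H x W x C, w C x L, b length L
ad_conv_pw <- function(x, w, b) {
  vx <- ad_val(x); vw <- ad_val(w); vb <- ad_val(b)
  d <- dim(vx); L <- ncol(vw)
  X2 <- matrix(vx, d[1] * d[2], d[3])
  Y2 <- sweep(X2 %*% vw, 2, vb, "+")
  ad_node(array(Y2, c(d[1], d[2], L)), function(g) {
    g2 <- matrix(g, d[1] * d[2], L)
    ad_accum(x, array(g2 %*% t(vw), d))
    ad_accum(w, t(X2) %*% g2)
    ad_accum(b, colSums(g2))
  })
}

# multi-channel-in, single-map-out convolution (CBAM spatial attention)
ad_conv_flat <- function(x, w, b) {
  vx <- ad_val(x); vw <- ad_val(w); vb <- ad_val(b)
  d <- dim(vx); k <- dim(vw)[1]; h <- (k - 1) %/% 2
  y <- matrix(vb, d[1], d[2])
  for (c in seq_len(d[3])) {
    xc <- vx[, , c]
    for (m in -h:h) for (n in -h:h) {
      y <- y + vw[m + h + 1, n + h + 1, c] * shift_array(xc, c(-m, -n),
                                                         fill = 0)
    }
  }
  ad_node(y, function(g) {
    gx <- array(0, d)
    gw <- array(0, dim(vw))
    for (c in seq_len(d[3])) {
      xc <- vx[, , c]
      for (m in -h:h) for (n in -h:h) {
        gx[, , c] <- gx[, , c] +
          vw[m + h + 1, n + h + 1, c] * shift_array(g, c(m, n), fill = 0)
        gw[m + h + 1, n + h + 1, c] <-
          sum(g * shift_array(xc, c(-m, -n), fill = 0))
      }
    }
    ad_accum(x, gx)
    ad_accum(w, gw)
    ad_accum(b, sum(g))
  })
}

# non-overlapping p x p max pooling per channel (H, W divisible by p)
ad_maxpool <- function(x, p) {
  vx <- ad_val(x)
  d <- dim(vx)
  if (d[1] %% p != 0 || d[2] %% p != 0) {
    stop("maxpool: spatial size not divisible by pool ", p)
  }
  ho <- d[1] %/% p; wo <- d[2] %/% p
  y <- array(-Inf, c(ho, wo, d[3]))
  arg <- array(0L, c(ho, wo, d[3]))
  for (di in seq_len(p)) for (dj in seq_len(p)) {
    sub <- vx[seq(di, d[1], by = p), seq(dj, d[2], by = p), , drop = FALSE]
    upd <- sub > y
    y[upd] <- sub[upd]
    arg[upd] <- (di - 1L) * p + dj
  }
  ad_node(y, function(g) {
    gx <- array(0, d)
    for (di in seq_len(p)) for (dj in seq_len(p)) {
      sel <- arg == (di - 1L) * p + dj
      gi <- array(0, dim(g))
      gi[sel] <- g[sel]
      gx[seq(di, d[1], by = p), seq(dj, d[2], by = p), ] <- gi
    }
    ad_accum(x, gx)
  })
}

# global average / max pooling over space: H x W x C -> 1 x C
ad_gap <- function(x) {
  vx <- ad_val(x)
  d <- dim(vx)
  y <- matrix(apply(vx, 3, mean), 1, d[3])
  ad_node(y, function(g) {
    gx <- array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), d)
    ad_accum(x, gx)
  })
}

ad_gmp <- function(x) {
  vx <- ad_val(x)
  d <- dim(vx)
  flat <- matrix(vx, d[1] * d[2], d[3])
  arg <- max.col(t(flat), ties.method = "first")
  y <- matrix(flat[cbind(arg, seq_len(d[3]))], 1, d[3])
  ad_node(y, function(g) {
    gx <- array(0, d)
    gf <- matrix(gx, d[1] * d[2], d[3])
    gf[cbind(arg, seq_len(d[3]))] <- g
    ad_accum(x, array(gf, d))
  })
}

# mean / max over channels: H x W x C -> H x W
ad_chanmean <- function(x) {
  vx <- ad_val(x)
  d <- dim(vx)
  y <- apply(vx, c(1, 2), mean)
  ad_node(y, function(g) {
    ad_accum(x, array(rep(g / d[3], times = d[3]), d))
  })
}

ad_chanmax <- function(x) {
  vx <- ad_val(x)
  d <- dim(vx)
  flat <- matrix(vx, d[1] * d[2], d[3])
  arg <- max.col(flat, ties.method = "first")
  y <- matrix(flat[cbind(seq_len(d[1] * d[2]), arg)], d[1], d[2])
  ad_node(y, function(g) {
    gf <- matrix(0, d[1] * d[2], d[3])
    gf[cbind(seq_len(d[1] * d[2]), arg)] <- as.vector(g)
    ad_accum(x, array(gf, d))
  })
}

# broadcasting multiplies for attention maps
ad_mul_channel <- function(x, s) {  # s: 1 x C
  vx <- ad_val(x); vs <- ad_val(s)
  d <- dim(vx)
  y <- vx * array(rep(vs, each = d[1] * d[2]), d)
  ad_node(y, function(g) {
    ad_accum(x, g * array(rep(vs, each = d[1] * d[2]), d))
    ad_accum(s, matrix(apply(g * vx, 3, sum), 1, d[3]))
  })
}

# stack K H x W maps into an H x W x K array
ad_stack_maps <- function(lst) {
  vals <- lapply(lst, ad_val)
  d <- dim(vals[[1]])
  ad_node(array(unlist(vals), c(d, length(vals))), function(g) {
    for (i in seq_along(lst)) ad_accum(lst[[i]], g[, , i])
  })
}

ad_mul_spatial <- function(x, m) {  # m: H x W
  vx <- ad_val(x); vm <- ad_val(m)
  d <- dim(vx)
  mm <- array(rep(vm, times = d[3]), d)
  ad_node(vx * mm, function(g) {
    ad_accum(x, g * mm)
    ad_accum(m, apply(g * vx, c(1, 2), sum))
  })
}
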