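# Minimal channels-first CNN engine.
#
# Feature maps are dense arrays of dim (C, H, W, B): channels, space, time,
# batch. 1-D stages keep H = 1. Convolutions are lowered to matrix products
# via im2col so the heavy lifting runs in BLAS; every operation has an
# explicit backward pass. Nothing here depends on an external deep-learning
# runtime.

.im2col_cache <- new.env(parent = emptyenv())

# Linear gather indices turning one (C,H,W) sample into the im2col matrix
# of a valid (kh,kw) convolution: K = C*kh*kw rows, P = OH*OW columns.
im2col_index <- function(C, H, W, kh, kw) {
  key <- paste(C, H, W, kh, kw, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  OH <- H - kh + 1L; OW <- W - kw + 1L
  k_c <- rep(seq_len(C), times = kh * kw)
  k_dh <- rep(rep(seq_len(kh), each = C), times = kw)
  k_dw <- rep(seq_len(kw), each = C * kh)
  p_oh <- rep(seq_len(OH), times = OW)
  p_ow <- rep(seq_len(OW), each = OH)
  rowpart <- k_c + C * (k_dh - 2L) + C * H * (k_dw - 2L)
  colpart <- C * p_oh + C * H * p_ow
  idx <- outer(rowpart, colpart, "+")
  .im2col_cache[[key]] <- idx
  idx
}

im2col <- function(x, kh, kw) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  key <- paste(C, H, W, kh, kw, B, sep = "_")
  gather <- .im2col_cache[[key]]
  if (is.null(gather)) {
    idx <- im2col_index(C, H, W, kh, kw)
    S <- C * H * W
    gather <- rep.int(as.vector(idx), B) +
      rep((seq_len(B) - 1L) * S, each = length(idx))
    dim(gather) <- c(nrow(idx), ncol(idx) * B)
    .im2col_cache[[key]] <- gather
  }
  cols <- x[gather]
  dim(cols) <- dim(gather)
  cols
}

# Standard convolution, valid padding. W is stored as a (C*kh*kw) x Cout
# matrix (rows ordered channel-fastest, then kh, then kw); b has length Cout.
conv2d_f <- function(x, W, b, kh, kw) {
  d <- dim(x)
  OH <- d[2] - kh + 1L; OW <- d[3] - kw + 1L
  cols <- im2col(x, kh, kw)
  y <- crossprod(W, cols) + b
  dim(y) <- c(ncol(W), OH, OW, d[4])
  list(y = y, cols = cols, xdim = d, kh = kh, kw = kw)
}

conv2d_b <- function(dy, cache, W, need_dx = TRUE) {
  d <- dim(dy); Cout <- d[1]
  dy_mat <- dy; dim(dy_mat) <- c(Cout, length(dy) / Cout)
  dW <- tcrossprod(cache$cols, dy_mat)
  db <- rowSums(dy_mat)
  dx <- NULL
  if (need_dx) {
    xd <- cache$xdim; C <- xd[1]
    kh <- cache$kh; kw <- cache$kw
    OH <- d[2]; OW <- d[3]
    dx <- array(0, xd)
    for (dw_ in seq_len(kw)) for (dh_ in seq_len(kh)) {
      rsel <- (dw_ - 1L) * C * kh + (dh_ - 1L) * C + seq_len(C)
      contrib <- Wsub_mult(W[rsel, , drop = FALSE], dy_mat)
      dim(contrib) <- c(C, OH, OW, xd[4])
      dx[, dh_:(dh_ + OH - 1L), dw_:(dw_ + OW - 1L), ] <-
        dx[, dh_:(dh_ + OH - 1L), dw_:(dw_ + OW - 1L), , drop = FALSE] +
        contrib
    }
  }
  list(dx = dx, dW = dW, db = db)
}

Wsub_mult <- function(Wsub, dy_mat) Wsub %*% dy_mat

# Depthwise convolution along the H axis, kernel (kh, 1): one (kh)-tap
# filter per channel. Wd is C x kh, bd length C.
dw_h_f <- function(x, Wd, bd) {
  d <- dim(x); kh <- ncol(Wd); OH <- d[2] - kh + 1L
  y <- array(0, c(d[1], OH, d[3], d[4]))
  for (dh in seq_len(kh))
    y <- y + x[, dh:(dh + OH - 1L), , , drop = FALSE] * Wd[, dh]
  y <- y + bd
  list(y = y, x = x, kh = kh)
}

dw_h_b <- function(dy, cache, Wd) {
  x <- cache$x; d <- dim(x); kh <- cache$kh
  OH <- dim(dy)[2]; C <- d[1]
  dWd <- matrix(0, C, kh)
  dx <- array(0, d)
  dbd <- rowSums(matrix(dy, C))
  for (dh in seq_len(kh)) {
    xs <- x[, dh:(dh + OH - 1L), , , drop = FALSE]
    dWd[, dh] <- rowSums(matrix(dy * xs, C))
    dx[, dh:(dh + OH - 1L), , ] <-
      dx[, dh:(dh + OH - 1L), , , drop = FALSE] + dy * Wd[, dh]
  }
  list(dx = dx, dW = dWd, db = dbd)
}

# Depthwise convolution along the W axis, kernel (1, kw).
dw_w_f <- function(x, Wd, bd) {
  d <- dim(x); kw <- ncol(Wd); OW <- d[3] - kw + 1L
  y <- array(0, c(d[1], d[2], OW, d[4]))
  for (dw_ in seq_len(kw))
    y <- y + x[, , dw_:(dw_ + OW - 1L), , drop = FALSE] * Wd[, dw_]
  y <- y + bd
  list(y = y, x = x, kw = kw)
}

dw_w_b <- function(dy, cache, Wd) {
  x <- cache$x; d <- dim(x); kw <- cache$kw
  OW <- dim(dy)[3]; C <- d[1]
  dWd <- matrix(0, C, kw)
  dx <- array(0, d)
  dbd <- rowSums(matrix(dy, C))
  for (dw_ in seq_len(kw)) {
    xs <- x[, , dw_:(dw_ + OW - 1L), , drop = FALSE]
    dWd[, dw_] <- rowSums(matrix(dy * xs, C))
    dx[, , dw_:(dw_ + OW - 1L), ] <-
      dx[, , dw_:(dw_ + OW - 1L), , drop = FALSE] + dy * Wd[, dw_]
  }
  list(dx = dx, dW = dWd, db = dbd)
}

# Pointwise (1x1) convolution mixing channels: Wp is Cout x Cin.
pw_f <- function(x, Wp, bp) {
  d <- dim(x); Cin <- d[1]
  xm <- x; dim(xm) <- c(Cin, length(x) / Cin)
  y <- Wp %*% xm + bp
  dim(y) <- c(nrow(Wp), d[-1])
  list(y = y, xm = xm, xdim = d)
}

pw_b <- function(dy, cache, Wp) {
  Cout <- nrow(Wp)
  dym <- dy; dim(dym) <- c(Cout, length(dy) / Cout)
  dW <- tcrossprod(dym, cache$xm)
  db <- rowSums(dym)
  dx <- crossprod(Wp, dym)
  dim(dx) <- cache$xdim
  list(dx = dx, dW = dW, db = db)
}

# Average pooling along the W (time) axis, width = stride = p, floor mode.
# The compiled kernels view (C, H, W, B) as (M, W, B) with M = C * H.
avgpool_w_f <- function(x, p) {
  d <- dim(x); To <- d[3] %/% p
  y <- cpp_avgpool_w(x, d[1] * d[2], d[3], d[4], p)
  dim(y) <- c(d[1], d[2], To, d[4])
  list(y = y, xdim = d, p = p)
}

avgpool_w_b <- function(dy, cache) {
  d <- cache$xdim
  dx <- cpp_avgpool_w_grad(dy, d[1] * d[2], d[3], d[4], cache$p)
  dim(dx) <- d
  dx
}

# Max pooling along the W axis, width = stride = p, floor mode.
maxpool_w_f <- function(x, p) {
  d <- dim(x); To <- d[3] %/% p
  r <- cpp_maxpool_w(x, d[1] * d[2], d[3], d[4], p)
  y <- r$y
  dim(y) <- c(d[1], d[2], To, d[4])
  list(y = y, arg = r$arg, xdim = d, p = p)
}

maxpool_w_b <- function(dy, cache) {
  d <- cache$xdim
  dx <- cpp_maxpool_w_grad(dy, cache$arg, d[1] * d[2], d[3], d[4],
                           cache$p)
  dim(dx) <- d
  dx
}

# Batch normalization over the leading (channel) axis of any array.
bn_f <- function(x, prm, training, momentum = 0.1, eps = 1e-5) {
  C <- dim(x)[1]
  m <- x; dim(m) <- c(C, length(x) / C)
  if (training) {
    mu <- rowMeans(m)
    v <- rowMeans(m * m) - mu^2
    v <- pmax(v, 0)
    N <- ncol(m)
    prm$rmean <- (1 - momentum) * prm$rmean + momentum * mu
    unb <- if (N > 1) v * N / (N - 1) else v
    prm$rvar <- (1 - momentum) * prm$rvar + momentum * unb
  } else {
    mu <- prm$rmean
    v <- prm$rvar
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (m - mu) * invstd
  y <- prm$gamma * xhat + prm$beta
  dim(y) <- dim(x)
  list(y = y, xhat = xhat, invstd = invstd, gamma = prm$gamma,
       training = training, xdim = dim(x), prm = prm)
}

bn_b <- function(dy, cache) {
  C <- cache$xdim[1]
  dym <- dy; dim(dym) <- c(C, length(dy) / C)
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  if (cache$training) {
    dxhat <- dym * cache$gamma
    dx <- cache$invstd *
      (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  } else {
    dx <- dym * cache$gamma * cache$invstd
  }
  dim(dx) <- cache$xdim
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

lrelu_f <- function(x, slope) {
  y <- cpp_lrelu(x, slope)
  dim(y) <- dim(x)
  list(y = y, x = x, slope = slope)
}

lrelu_b <- function(dy, cache) {
  dx <- cpp_lrelu_grad(dy, cache$x, cache$slope)
  dim(dx) <- dim(dy)
  dx
}

relu_f <- function(x) {
  pos <- x > 0
  list(y = x * pos, pos = pos)
}

relu_b <- function(dy, cache) dy * cache$pos

dropout_f <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

dropout_b <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

linear_f <- function(x, W, b) list(y = W %*% x + b, x = x)

linear_b <- function(dy, cache, W) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

# Column-wise softmax of a K x B matrix of logits.
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# ---- parameter initialization and the Adam optimizer -----------------------

# Fan-in-scaled uniform init (the conventional default for conv/linear
# layers); draws from the current RNG stream.
init_mat <- function(nrow, ncol, fan_in) {
  a <- sqrt(1 / fan_in)
  matrix(stats::runif(nrow * ncol, -a, a), nrow, ncol)
}

init_vec <- function(n, fan_in) {
  a <- sqrt(1 / fan_in)
  stats::runif(n, -a, a)
}

init_bn <- function(C) list(gamma = rep(1, C), beta = rep(0, C),
                            rmean = rep(0, C), rvar = rep(1, C))

# Recursively zero a gradient/optimizer-state tree shaped like `tree`,
# keeping only trainable leaves (W, b, gamma, beta).
zeros_like_trainable <- function(tree) {
  if (is.list(tree)) {
    out <- lapply(tree, zeros_like_trainable)
    out[!vapply(out, is.null, logical(1))]
  } else if (is.null(dim(tree))) {
    numeric(length(tree))
  } else {
    array(0, dim = dim(tree))
  }
}

.trainable_names <- c("W", "b", "gamma", "beta")

# Extract the trainable sub-tree (used to shape Adam state).
trainable_tree <- function(tree) {
  if (!is.list(tree)) return(tree)
  out <- list()
  for (nm in names(tree)) {
    v <- tree[[nm]]
    if (is.list(v)) {
      sub <- trainable_tree(v)
      if (length(sub)) out[[nm]] <- sub
    } else if (nm %in% .trainable_names) {
      out[[nm]] <- v
    }
  }
  out
}

adam_init <- function(params) {
  tt <- trainable_tree(params)
  list(m = zeros_like_trainable(tt), v = zeros_like_trainable(tt), t = 0L)
}

# One Adam update. `grads` must mirror the trainable sub-tree of `params`.
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(g)) {
      for (nm in names(g)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# Elementwise sum of two gradient trees (for accumulating branch grads).
tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (nm in names(b)) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
    a
  } else a + b
}
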