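#' Model configuration
#'
#' Hyperparameters of the multi-scale spatio-temporal convolutional
#' network. The temporal stage applies `n_temporal_scales` parallel valid
#' convolutions with kernel widths `floor(m^i * f)`, leaky rectification
#' and average pooling, concatenated along the time axis; the spatial stage
#' applies a global `(c, 1)` and a local `(floor(m * c), 1)` kernel
#' concatenated along the space axis; the fusion stage is a stack of
#' separable-convolution blocks; the classifier head is three fully
#' connected layers with batch normalization and dropout.
#'
#' @param c Number of channels (electrodes) per window.
#' @param f Window length in samples (128 or 100 for the two canonical
#'   geometries).
#' @param m Multi-scale factor in `(0, 1)`.
#' @param n_temporal_scales Number of temporal kernel scales.
#' @param temporal_filters,temporal_pool Temporal-stage filter count and
#'   average-pooling width (= stride).
#' @param spatial_filters,spatial_pool Spatial-stage filter count and
#'   average-pooling width.
#' @param spatial_mode `"both"` (global + local kernels) or `"global"`.
#' @param use_fusion Include the separable-convolution fusion stage.
#' @param ffl_channels Output channels of the four fusion blocks.
#' @param ffl_kernel Depthwise kernel length in the fusion blocks.
#' @param ffl_pool Max-pooling widths of the four fusion blocks.
#' @param dcl_hidden Hidden sizes of the classifier head.
#' @param n_classes 2 (binary) or 4 (quadrant).
#' @param dropout Dropout rate in the classifier head.
#' @param negative_slope Leaky-rectifier slope in the conv stages.
#' @return An object of class `model_config`.
#' @export
model_config <- function(c = 4L, f = 128L, m = 0.5, n_temporal_scales = 3L,
                         temporal_filters = 128L, temporal_pool = 8L,
                         spatial_filters = 15L, spatial_pool = 2L,
                         spatial_mode = c("both", "global"),
                         use_fusion = TRUE,
                         ffl_channels = c(15L, 32L, 64L, 128L),
                         ffl_kernel = 3L, ffl_pool = c(4L, 2L, 2L, 2L),
                         dcl_hidden = c(64L, 16L), n_classes = 2L,
                         dropout = 0.5, negative_slope = 0.01) {
  spatial_mode <- match.arg(spatial_mode)
  stop_if_not(m > 0 && m < 1, "m must be in (0, 1)")
  stop_if_not(c >= 1 && f >= 2, "need c >= 1 and f >= 2")
  cfg <- structure(list(
    c = as.integer(c), f = as.integer(f), m = m,
    n_temporal_scales = as.integer(n_temporal_scales),
    temporal_filters = as.integer(temporal_filters),
    temporal_pool = as.integer(temporal_pool),
    spatial_filters = as.integer(spatial_filters),
    spatial_pool = as.integer(spatial_pool),
    spatial_mode = spatial_mode, use_fusion = isTRUE(use_fusion),
    ffl_channels = as.integer(ffl_channels),
    ffl_kernel = as.integer(ffl_kernel), ffl_pool = as.integer(ffl_pool),
    dcl_hidden = as.integer(dcl_hidden), n_classes = as.integer(n_classes),
    dropout = dropout, negative_slope = negative_slope
  ), class = "model_config")
  model_shapes(cfg)  # validates every stage has positive extent
  cfg
}

#' Temporal kernel widths of the multi-scale rule
#'
#' Width of scale `i` is `floor(m^i * f)`, for `i = 1..n`.
#'
#' @param f Window length in samples.
#' @param m Scale factor in `(0, 1)`.
#' @param n Number of scales.
#' @return Integer vector of kernel widths (largest first).
#' @export
temporal_kernel_widths <- function(f, m = 0.5, n = 3) {
  stop_if_not(f >= 2 && m > 0 && m < 1 && n >= 1,
              "need f >= 2, m in (0,1), n >= 1")
  w <- floor(m^seq_len(n) * f)
  stop_if_not(all(w >= 1), "kernel width below 1 at f=%d, m=%g, n=%d",
              f, m, n)
  as.integer(w)
}

#' Closed-form shape trace of the network
#'
#' Computes the output extent of every stage analytically (valid
#' convolutions, floor-mode pooling). Used to size parameters and checked
#' in tests against the dimensions observed in executed forward passes.
#'
#' @param cfg A [model_config()].
#' @return A list with per-stage shape descriptors, including
#'   `temporal_len` (concatenated time length after the temporal stage) and
#'   `dcl_in` (flattened classifier input size).
#' @export
model_shapes <- function(cfg) {
  widths <- temporal_kernel_widths(cfg$f, cfg$m, cfg$n_temporal_scales)
  branch_len <- (cfg$f - widths + 1L) %/% cfg$temporal_pool
  stop_if_not(all(branch_len >= 1),
              "temporal pooling empties a branch (f=%d)", cfg$f)
  Lt <- sum(branch_len)
  # spatial stage
  kh_local <- max(1L, floor(cfg$m * cfg$c))
  rows <- if (cfg$spatial_mode == "both") {
    stop_if_not(kh_local <= cfg$c, "local spatial kernel exceeds channels")
    c(1L, cfg$c - kh_local + 1L)
  } else 1L
  S <- sum(rows)
  Ls <- Lt %/% cfg$spatial_pool
  stop_if_not(Ls >= 1, "spatial pooling empties the time axis")
  fusion <- NULL
  if (cfg$use_fusion) {
    k1 <- min(cfg$ffl_kernel, S)
    S1 <- S - k1 + 1L
    T1 <- Ls %/% cfg$ffl_pool[1]
    stop_if_not(S1 >= 1 && T1 >= 1, "fusion block 1 empties its input")
    flat <- cfg$ffl_channels[1] * S1 * T1
    lens <- integer(4); lens[1] <- flat
    for (q in 2:4) {
      conv_len <- lens[q - 1] - cfg$ffl_kernel + 1L
      stop_if_not(conv_len >= 1, "fusion block %d kernel exceeds its input", q)
      lens[q] <- conv_len %/% cfg$ffl_pool[q]
      stop_if_not(lens[q] >= 1, "fusion block %d empties its input", q)
    }
    fusion <- list(k1 = k1, space1 = S1, time1 = T1, flat = flat,
                   lens = lens)
    dcl_in <- cfg$ffl_channels[4] * lens[4]
  } else {
    dcl_in <- cfg$spatial_filters * S * Ls
  }
  list(widths = widths, branch_len = branch_len, temporal_len = Lt,
       temporal = c(cfg$temporal_filters, cfg$c, Lt),
       spatial_rows = rows, spatial = c(cfg$spatial_filters, S, Ls),
       fusion = fusion, dcl_in = as.integer(dcl_in))
}

#' Initialize model parameters
#'
#' Fan-in-scaled uniform initialization of every convolutional and linear
#' layer, seed-controlled; batch-norm scales start at 1 with zeroed shifts.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed.
#' @return An object of class `tscl_model`: a list with `config` and
#'   `params` (nested named parameter arrays).
#' @export
model_init <- function(cfg, seed = 42) {
  sh <- model_shapes(cfg)
  params <- with_seed(seed, {
    p <- list()
    p$temporal <- list()
    for (i in seq_len(cfg$n_temporal_scales)) {
      k <- sh$widths[i]
      p$temporal[[paste0("branch", i)]] <- list(
        W = init_mat(k, cfg$temporal_filters, k),
        b = init_vec(cfg$temporal_filters, k))
    }
    p$temporal$bn <- init_bn(cfg$temporal_filters)
    tf <- cfg$temporal_filters
    p$spatial <- list(global = list(
      W = init_mat(tf * cfg$c, cfg$spatial_filters, tf * cfg$c),
      b = init_vec(cfg$spatial_filters, tf * cfg$c)))
    if (cfg$spatial_mode == "both") {
      khl <- max(1L, floor(cfg$m * cfg$c))
      p$spatial$local <- list(
        W = init_mat(tf * khl, cfg$spatial_filters, tf * khl),
        b = init_vec(cfg$spatial_filters, tf * khl))
    }
    p$spatial$bn <- init_bn(cfg$spatial_filters)
    if (cfg$use_fusion) {
      sf <- cfg$spatial_filters
      fc1 <- cfg$ffl_channels[1]
      p$fusion <- list(b1 = list(
        dw = list(W = init_mat(sf, sh$fusion$k1, sh$fusion$k1),
                  b = init_vec(sf, sh$fusion$k1)),
        pw = list(W = init_mat(fc1, sf, sf), b = init_vec(fc1, sf)),
        bn = init_bn(fc1)))
      in_ch <- 1L
      for (q in 2:4) {
        out_ch <- cfg$ffl_channels[q]
        p$fusion[[paste0("b", q)]] <- list(
          dw = list(W = init_mat(in_ch, cfg$ffl_kernel, cfg$ffl_kernel),
                    b = init_vec(in_ch, cfg$ffl_kernel)),
          pw = list(W = init_mat(out_ch, in_ch, in_ch),
                    b = init_vec(out_ch, in_ch)),
          bn = init_bn(out_ch))
        in_ch <- out_ch
      }
    }
    h <- cfg$dcl_hidden
    p$classifier <- list(
      fc1 = list(W = init_mat(h[1], sh$dcl_in, sh$dcl_in),
                 b = init_vec(h[1], sh$dcl_in)),
      bn1 = init_bn(h[1]),
      fc2 = list(W = init_mat(h[2], h[1], h[1]), b = init_vec(h[2], h[1])),
      bn2 = init_bn(h[2]),
      fc3 = list(W = init_mat(cfg$n_classes, h[2], h[2]),
                 b = init_vec(cfg$n_classes, h[2])))
    p
  })
  structure(list(config = cfg, params = params, seed = as.integer(seed)),
            class = "tscl_model")
}

#' @export
print.tscl_model <- function(x, ...) {
  sh <- model_shapes(x$config)
  cat(sprintf(
    "<tscl_model> c=%d f=%d | temporal widths %s -> len %d | spatial %s | dcl_in %d | %d classes\n",
    x$config$c, x$config$f, paste(sh$widths, collapse = "/"),
    sh$temporal_len, paste(sh$spatial, collapse = "x"), sh$dcl_in,
    x$config$n_classes))
  invisible(x)
}

# Convert an n x c x f window stack into the model's input layout
# (1, c, f, batch).
input_array <- function(X) {
  d <- dim(X)
  x <- aperm(X, c(2, 3, 1))
  dim(x) <- c(1L, d[2], d[3], d[1])
  x
}

#' Forward pass
#'
#' Runs the full network on a stack of windows. In training mode, batch
#' normalization uses batch statistics (and updates its running statistics,
#' returned via the `params` element) and dropout is active; in eval mode
#' the pass is deterministic.
#'
#' @param model A [model_init()] model.
#' @param X Either an `n x c x f` array of windows or a pre-converted
#'   `(1, c, f, n)` input array.
#' @param training Logical; batch-statistics normalization and (by
#'   default) dropout.
#' @param bn_momentum Running-statistics update momentum used when
#'   `training = TRUE` (1 replaces them with the current batch statistics;
#'   see [calibrate_bn()]).
#' @param use_dropout Whether dropout is active (defaults to `training`;
#'   calibration passes disable it).
#' @return A list with `probs` (n x n_classes matrix, rows summing to 1),
#'   `logits`, `cache` (for the backward pass), `stages` (observed stage
#'   output shapes) and `params` (with updated normalization buffers).
#' @export
tscl_forward <- function(model, X, training = FALSE, bn_momentum = 0.1,
                         use_dropout = training) {
  cfg <- model$config
  p <- model$params
  x0 <- if (length(dim(X)) == 3) input_array(X) else X
  stop_if_not(dim(x0)[2] == cfg$c && dim(x0)[3] == cfg$f,
              "input is %d x %d but the model expects c=%d, f=%d",
              dim(x0)[2], dim(x0)[3], cfg$c, cfg$f)
  sh <- model_shapes(cfg)
  B <- dim(x0)[4]
  ca <- list()

  # temporal stage: parallel multi-scale convolutions, concat along time
  tb <- vector("list", cfg$n_temporal_scales)
  ycat <- array(0, c(cfg$temporal_filters, cfg$c, sh$temporal_len, B))
  pos <- 0L
  for (i in seq_len(cfg$n_temporal_scales)) {
    br <- p$temporal[[paste0("branch", i)]]
    cv <- conv2d_f(x0, br$W, br$b, 1L, sh$widths[i])
    ac <- lrelu_f(cv$y, cfg$negative_slope)
    pl <- avgpool_w_f(ac$y, cfg$temporal_pool)
    len <- dim(pl$y)[3]
    ycat[, , (pos + 1L):(pos + len), ] <- pl$y
    tb[[i]] <- list(cv = cv, ac = ac, pl = pl, from = pos + 1L,
                    to = pos + len)
    pos <- pos + len
  }
  bnT <- bn_f(ycat, p$temporal$bn, training, bn_momentum)
  p$temporal$bn <- bnT$prm
  ca$temporal <- list(branches = tb, bn = bnT)
  xT <- bnT$y

  # spatial stage: global + local kernels, concat along space
  kh_local <- max(1L, floor(cfg$m * cfg$c))
  sg <- conv2d_f(xT, p$spatial$global$W, p$spatial$global$b, cfg$c, 1L)
  ag <- lrelu_f(sg$y, cfg$negative_slope)
  pg <- avgpool_w_f(ag$y, cfg$spatial_pool)
  S <- sum(sh$spatial_rows)
  Ls <- dim(pg$y)[3]
  scat <- array(0, c(cfg$spatial_filters, S, Ls, B))
  scat[, 1L, , ] <- pg$y
  sl <- NULL
  if (cfg$spatial_mode == "both") {
    cl <- conv2d_f(xT, p$spatial$local$W, p$spatial$local$b, kh_local, 1L)
    al <- lrelu_f(cl$y, cfg$negative_slope)
    pl <- avgpool_w_f(al$y, cfg$spatial_pool)
    scat[, 2L:S, , ] <- pl$y
    sl <- list(cv = cl, ac = al, pl = pl)
  }
  bnS <- bn_f(scat, p$spatial$bn, training, bn_momentum)
  p$spatial$bn <- bnS$prm
  ca$spatial <- list(global = list(cv = sg, ac = ag, pl = pg), local = sl,
                     bn = bnS, S = S)
  xS <- bnS$y

  # fusion stage: separable-convolution blocks
  if (cfg$use_fusion) {
    f1 <- p$fusion$b1
    d1 <- dw_h_f(xS, f1$dw$W, f1$dw$b)
    w1 <- pw_f(d1$y, f1$pw$W, f1$pw$b)
    n1 <- bn_f(w1$y, f1$bn, training, bn_momentum)
    p$fusion$b1$bn <- n1$prm
    r1 <- relu_f(n1$y)
    m1 <- maxpool_w_f(r1$y, cfg$ffl_pool[1])
    flat_dim <- dim(m1$y)
    z <- m1$y
    dim(z) <- c(1L, 1L, prod(flat_dim[1:3]), flat_dim[4])
    ca$fusion <- list(b1 = list(dw = d1, pw = w1, bn = n1, rl = r1,
                                mp = m1, flat_dim = flat_dim))
    for (q in 2:4) {
      fq <- p$fusion[[paste0("b", q)]]
      dq <- dw_w_f(z, fq$dw$W, fq$dw$b)
      wq <- pw_f(dq$y, fq$pw$W, fq$pw$b)
      nq <- bn_f(wq$y, fq$bn, training, bn_momentum)
      p$fusion[[paste0("b", q)]]$bn <- nq$prm
      rq <- relu_f(nq$y)
      mq <- maxpool_w_f(rq$y, cfg$ffl_pool[q])
      ca$fusion[[paste0("b", q)]] <- list(dw = dq, pw = wq, bn = nq,
                                          rl = rq, mp = mq)
      z <- mq$y
    }
    fusion_out_dim <- dim(z)
  } else {
    z <- xS
    fusion_out_dim <- NULL
  }

  # classifier head
  zdim <- dim(z)
  zmat <- z
  dim(zmat) <- c(prod(zdim[1:3]), zdim[4])
  cl <- p$classifier
  l1 <- linear_f(zmat, cl$fc1$W, cl$fc1$b)
  n1c <- bn_f(l1$y, cl$bn1, training, bn_momentum)
  p$classifier$bn1 <- n1c$prm
  r1c <- relu_f(n1c$y)
  o1 <- dropout_f(r1c$y, cfg$dropout, use_dropout)
  l2 <- linear_f(o1$y, cl$fc2$W, cl$fc2$b)
  n2c <- bn_f(l2$y, cl$bn2, training, bn_momentum)
  p$classifier$bn2 <- n2c$prm
  r2c <- relu_f(n2c$y)
  o2 <- dropout_f(r2c$y, cfg$dropout, use_dropout)
  l3 <- linear_f(o2$y, cl$fc3$W, cl$fc3$b)
  logits <- l3$y
  probs <- t(softmax_cols(logits))
  ca$classifier <- list(zdim = zdim, l1 = l1, bn1 = n1c, r1 = r1c, o1 = o1,
                        l2 = l2, bn2 = n2c, r2 = r2c, o2 = o2, l3 = l3)

  stages <- list(temporal = dim(xT), spatial = dim(xS),
                 fusion = fusion_out_dim, dcl_in = nrow(zmat))
  list(probs = probs, logits = logits, cache = ca, stages = stages,
       params = p)
}

# Backward pass from d(logits): returns the gradient tree over trainable
# parameters. `cache` and `params` must come from the same tscl_forward call.
tscl_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  g <- list()
  cc <- cache$classifier
  b3 <- linear_b(dlogits, cc$l3, p$classifier$fc3$W)
  d <- dropout_b(b3$dx, cc$o2)
  d <- relu_b(d, cc$r2)
  bb2 <- bn_b(d, cc$bn2)
  b2 <- linear_b(bb2$dx, cc$l2, p$classifier$fc2$W)
  d <- dropout_b(b2$dx, cc$o1)
  d <- relu_b(d, cc$r1)
  bb1 <- bn_b(d, cc$bn1)
  b1 <- linear_b(bb1$dx, cc$l1, p$classifier$fc1$W)
  g$classifier <- list(
    fc3 = list(W = b3$dW, b = b3$db),
    bn2 = list(gamma = bb2$dgamma, beta = bb2$dbeta),
    fc2 = list(W = b2$dW, b = b2$db),
    bn1 = list(gamma = bb1$dgamma, beta = bb1$dbeta),
    fc1 = list(W = b1$dW, b = b1$db))
  dz <- b1$dx
  dim(dz) <- cc$zdim

  if (cfg$use_fusion) {
    g$fusion <- list()
    for (q in 4:2) {
      fq <- cache$fusion[[paste0("b", q)]]
      pq <- p$fusion[[paste0("b", q)]]
      d <- maxpool_w_b(dz, fq$mp)
      d <- relu_b(d, fq$rl)
      bb <- bn_b(d, fq$bn)
      pw <- pw_b(bb$dx, fq$pw, pq$pw$W)
      dw <- dw_w_b(pw$dx, fq$dw, pq$dw$W)
      g$fusion[[paste0("b", q)]] <- list(
        bn = list(gamma = bb$dgamma, beta = bb$dbeta),
        pw = list(W = pw$dW, b = pw$db),
        dw = list(W = dw$dW, b = dw$db))
      dz <- dw$dx
    }
    f1 <- cache$fusion$b1
    dim(dz) <- f1$flat_dim
    d <- maxpool_w_b(dz, f1$mp)
    d <- relu_b(d, f1$rl)
    bb <- bn_b(d, f1$bn)
    pw <- pw_b(bb$dx, f1$pw, p$fusion$b1$pw$W)
    dw <- dw_h_b(pw$dx, f1$dw, p$fusion$b1$dw$W)
    g$fusion$b1 <- list(bn = list(gamma = bb$dgamma, beta = bb$dbeta),
                        pw = list(W = pw$dW, b = pw$db),
                        dw = list(W = dw$dW, b = dw$db))
    dxS <- dw$dx
  } else {
    dxS <- dz
  }

  # spatial stage
  sp <- cache$spatial
  bbS <- bn_b(dxS, sp$bn)
  dcat <- bbS$dx
  dg <- dcat[, 1L, , , drop = FALSE]
  dpg <- avgpool_w_b(dg, sp$global$pl)
  dpg <- lrelu_b(dpg, sp$global$ac)
  cg <- conv2d_b(dpg, sp$global$cv, p$spatial$global$W, need_dx = TRUE)
  dxT <- cg$dx
  g$spatial <- list(global = list(W = cg$dW, b = cg$db),
                    bn = list(gamma = bbS$dgamma, beta = bbS$dbeta))
  if (cfg$spatial_mode == "both") {
    dl <- dcat[, 2L:sp$S, , , drop = FALSE]
    dpl <- avgpool_w_b(dl, sp$local$pl)
    dpl <- lrelu_b(dpl, sp$local$ac)
    clb <- conv2d_b(dpl, sp$local$cv, p$spatial$local$W, need_dx = TRUE)
    dxT <- dxT + clb$dx
    g$spatial$local <- list(W = clb$dW, b = clb$db)
  }

  # temporal stage (input layer: no dx needed)
  tp <- cache$temporal
  bbT <- bn_b(dxT, tp$bn)
  g$temporal <- list(bn = list(gamma = bbT$dgamma, beta = bbT$dbeta))
  for (i in seq_along(tp$branches)) {
    br <- tp$branches[[i]]
    dbr <- bbT$dx[, , br$from:br$to, , drop = FALSE]
    dpb <- avgpool_w_b(dbr, br$pl)
    dpb <- lrelu_b(dpb, br$ac)
    cb <- conv2d_b(dpb, br$cv, p$temporal[[paste0("branch", i)]]$W,
                   need_dx = FALSE)
    g$temporal[[paste0("branch", i)]] <- list(W = cb$dW, b = cb$db)
  }
  g
}

#' Ablation variant of the model configuration
#'
#' @param cfg A [model_config()].
#' @param drop `"temporal"` (single largest temporal kernel only),
#'   `"spatial"` (global spatial kernel only), `"fusion"` (flatten the
#'   spatial output straight into the classifier), or `"none"`.
#' @return A modified `model_config`.
#' @export
make_variant <- function(cfg, drop = c("none", "temporal", "spatial",
                                       "fusion")) {
  drop <- match.arg(drop)
  args <- unclass(cfg)
  switch(drop,
    none = cfg,
    temporal = do.call(model_config,
                       modifyList(args, list(n_temporal_scales = 1L))),
    spatial = do.call(model_config,
                      modifyList(args, list(spatial_mode = "global"))),
    fusion = do.call(model_config,
                     modifyList(args, list(use_fusion = FALSE))))
}

#' Recalibrate batch-normalization statistics
#'
#' Replaces every layer's running mean/variance with the cumulative
#' average of batch statistics observed over `X` (dropout disabled,
#' parameters untouched). Training loops at desk scale see few batches,
#' so the exponential running statistics would otherwise still be
#' dominated by their initialization; a calibration pass after training
#' makes eval-mode normalization reflect the data actually modeled.
#'
#' @param model A `tscl_model`.
#' @param X `n x c x f` array (typically the training windows).
#' @param batch_size Calibration batch size.
#' @return The model with updated normalization buffers.
#' @export
calibrate_bn <- function(model, X, batch_size = 256L) {
  n <- dim(X)[1]
  k <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, n)
    k <- k + 1L
    fw <- tscl_forward(model, X[bi, , , drop = FALSE], training = TRUE,
                       bn_momentum = 1 / k, use_dropout = FALSE)
    model$params <- fw$params
  }
  model
}

#' Predict class probabilities and labels
#'
#' Deterministic eval-mode forward pass, evaluated in chunks to bound
#' memory.
#'
#' @param model A trained [model_init()] model.
#' @param X `n x c x f` array of windows.
#' @param batch_size Evaluation chunk size.
#' @return A list with `probs` (n x K) and `labels` (integer argmax, ties
#'   to the first class).
#' @export
model_predict <- function(model, X, batch_size = 512L) {
  n <- dim(X)[1]
  probs <- matrix(0, n, model$config$n_classes)
  for (start in seq(1L, n, by = batch_size)) {
    bi <- start:min(start + batch_size - 1L, n)
    probs[bi, ] <- tscl_forward(model, X[bi, , , drop = FALSE],
                                training = FALSE)$probs
  }
  labels <- max.col(probs, ties.method = "first")
  list(probs = probs, labels = labels)
}

#' Save / load a model checkpoint
#'
#' Writes the parameter arrays plus a JSON manifest holding the
#' configuration, seed and phase tag. Round-trips bit-exactly.
#'
#' @param model A `tscl_model`.
#' @param path Directory to create/use.
#' @param phase Free-form tag (e.g. `"pretrained"`, `"finetuned"`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model with a `phase` attribute.
#' @export
save_model <- function(model, path, phase = "pretrained") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(path, "params.rds"))
  manifest <- list(config = unclass(model$config), seed = model$seed,
                   phase = phase, package = "eeglwf")
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  cfgl <- manifest$config
  cfg <- model_config(
    c = cfgl$c, f = cfgl$f, m = cfgl$m,
    n_temporal_scales = cfgl$n_temporal_scales,
    temporal_filters = cfgl$temporal_filters,
    temporal_pool = cfgl$temporal_pool,
    spatial_filters = cfgl$spatial_filters,
    spatial_pool = cfgl$spatial_pool, spatial_mode = cfgl$spatial_mode,
    use_fusion = cfgl$use_fusion, ffl_channels = cfgl$ffl_channels,
    ffl_kernel = cfgl$ffl_kernel, ffl_pool = cfgl$ffl_pool,
    dcl_hidden = cfgl$dcl_hidden, n_classes = cfgl$n_classes,
    dropout = cfgl$dropout, negative_slope = cfgl$negative_slope)
  model <- structure(list(config = cfg,
                          params = readRDS(file.path(path, "params.rds")),
                          seed = manifest$seed),
                     class = "tscl_model")
  attr(model, "phase") <- manifest$phase
  model
}
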