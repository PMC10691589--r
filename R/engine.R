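# Matrix-based neural network engine backing the model specifications.
# All heavy operations are expressed as BLAS matrix products on batched
# arrays; batches are laid out with the sample index fastest, so a
# B x T x D array viewed as a (B*T) x D matrix enumerates (sample, step)
# pairs consistently.

sigmoid <- function(x) 1 / (1 + exp(-x))

# B x T x u array -> B x u matrix at step t (keeps dims for B = 1)
slice_t <- function(A, t) matrix(A[, t, ], dim(A)[1], dim(A)[3])

glorot_uniform <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

orthogonal_init <- function(n) {
  qr_ <- qr(matrix(stats::rnorm(n * n), n))
  Q <- qr.Q(qr_)
  Q * rep(sign(diag(qr.R(qr_)) + 1e-12), each = n)
}

lstm_init <- function(input_dim, units) {
  Wh <- do.call(cbind, lapply(1:4, function(i) orthogonal_init(units)))
  b <- rep(0, 4 * units)
  b[units + seq_len(units)] <- 1          # forget-gate bias at 1
  list(Wx = glorot_uniform(input_dim, 4 * units),
       Wh = Wh, b = b)
}

# ---- primitive layers (forward returns a cache for backward) -------------

dense_fw <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- sweep(Y, 2, b, "+")
  list(Y = Y, cache = X)
}

dense_bw <- function(dY, W, cache, has_bias = TRUE) {
  list(dW = crossprod(cache, dY),
       db = if (has_bias) colSums(dY) else NULL,
       dX = tcrossprod(dY, W))
}

dropout_fw <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- array((stats::runif(length(X)) >= rate) / (1 - rate), dim = dim(X))
  list(Y = X * mask, mask = mask)
}

dropout_bw <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

batchnorm_fw <- function(X, gamma, beta, state, training,
                         momentum = 0.9, eps = 1e-3) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2, mu), 2, invstd, "*")
  Y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(Y = Y, state = state,
       cache = list(xhat = xhat, invstd = invstd, training = training))
}

batchnorm_bw <- function(dY, gamma, cache) {
  xhat <- cache$xhat
  B <- nrow(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, gamma, "*")
  if (cache$training) {
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
    dX <- sweep(t1 - t2, 2, cache$invstd, "*")
  } else {
    dX <- sweep(dxhat, 2, cache$invstd, "*")
  }
  list(dgamma = dgamma, dbeta = dbeta, dX = dX)
}

# LSTM forward over a B x T x D batch. Gate order (i, f, g, o). The cell
# recursion runs in compiled code; the input projection is one BLAS gemm.
lstm_fw <- function(X, p, return_sequences = FALSE) {
  dm <- dim(X); B <- dm[1]; Tn <- dm[2]; D <- dm[3]
  u <- nrow(p$Wh)
  Xm <- matrix(X, B * Tn, D)
  Zin <- sweep(Xm %*% p$Wx, 2, p$b, "+")
  out <- cpp_lstm_fw(Zin, p$Wh, B, Tn, return_sequences)
  list(H = if (return_sequences) out$Hs else NULL,
       h_last = out$h_last,
       cache = list(Xm = Xm, Hs = out$Hs, Cs = out$Cs, Ig = out$Ig,
                    Fg = out$Fg, Gg = out$Gg, Og = out$Og,
                    B = B, Tn = Tn, D = D, u = u))
}

# Backpropagation through time. `dH` is B x T x u (or NULL), `dh_last` is
# B x u (or NULL). Returns parameter gradients and optionally dX.
lstm_bw <- function(p, cache, dH = NULL, dh_last = NULL, want_dx = FALSE) {
  B <- cache$B; Tn <- cache$Tn
  res <- cpp_lstm_bw(p$Wh, cache$Hs, cache$Cs, cache$Ig, cache$Fg,
                     cache$Gg, cache$Og, dH, dh_last, B, Tn)
  list(dWx = crossprod(cache$Xm, res$DZ),
       dWh = res$dWh,
       db = as.numeric(res$db),
       dX = if (want_dx)
         array(res$DZ %*% t(p$Wx), c(B, Tn, cache$D)) else NULL)
}

# Temporal convolution with a k x 1 kernel over B x T x W x C input
# (shared across the width axis), TF-style "same" or "valid" padding.
# im2col/col2im run in compiled code; the contraction is one BLAS gemm.
conv_time_fw <- function(X, W, b, stride = 1L, padding = "same",
                         relu = TRUE) {
  dm <- dim(X); B <- dm[1]; Tn <- dm[2]; Wd <- dm[3]; C <- dm[4]
  k <- nrow(W) / C
  if (padding == "same") {
    Tout <- as.integer(ceiling(Tn / stride))
    pad_beg <- max((Tout - 1L) * stride + k - Tn, 0L) %/% 2L
  } else {
    Tout <- as.integer(floor((Tn - k) / stride) + 1L)
    pad_beg <- 0L
  }
  M <- cpp_im2col_time(X, B, Tn, Wd, C, k, stride, pad_beg, Tout)
  Y <- sweep(M %*% W, 2, b, "+")
  mask <- NULL
  if (relu) { mask <- Y > 0; Y <- Y * mask }
  list(Y = array(Y, c(B, Tout, Wd, ncol(W))),
       cache = list(M = M, mask = mask, B = B, Tn = Tn, Wd = Wd, C = C,
                    k = k, stride = stride, Tout = Tout,
                    pad_beg = pad_beg))
}

conv_time_bw <- function(dY, W, cache, want_dx = TRUE) {
  cc <- cache
  dYm <- matrix(dY, cc$B * cc$Tout * cc$Wd, ncol(W))
  if (!is.null(cc$mask)) dYm <- dYm * cc$mask
  dW <- crossprod(cc$M, dYm)
  db <- colSums(dYm)
  dX <- NULL
  if (want_dx) {
    dM <- tcrossprod(dYm, W)
    dX <- cpp_col2im_time(dM, cc$B, cc$Tn, cc$Wd, cc$C, cc$k,
                          cc$stride, cc$pad_beg, cc$Tout)
    dim(dX) <- c(cc$B, cc$Tn, cc$Wd, cc$C)
  }
  list(dW = dW, db = db, dX = dX)
}

# 1 x W "valid" convolution collapsing the width axis: a dense map per
# time step from (W * C) to F.
conv_width_fw <- function(X, W, b, relu = TRUE) {
  dm <- dim(X); B <- dm[1]; Tn <- dm[2]; Wd <- dm[3]; C <- dm[4]
  Xm <- matrix(X, B * Tn, Wd * C)
  Y <- sweep(Xm %*% W, 2, b, "+")
  mask <- NULL
  if (relu) { mask <- Y > 0; Y <- Y * mask }
  list(Y = array(Y, c(B, Tn, 1L, ncol(W))),
       cache = list(Xm = Xm, mask = mask, B = B, Tn = Tn, Wd = Wd, C = C))
}

conv_width_bw <- function(dY, W, cache, want_dx = TRUE) {
  cc <- cache
  dYm <- matrix(dY, cc$B * cc$Tn, ncol(W))
  if (!is.null(cc$mask)) dYm <- dYm * cc$mask
  list(dW = crossprod(cc$Xm, dYm),
       db = colSums(dYm),
       dX = if (want_dx)
         array(tcrossprod(dYm, W), c(cc$B, cc$Tn, cc$Wd, cc$C)) else NULL)
}

# 2 x 1 max pooling over time (valid; an odd trailing step is dropped).
maxpool2_fw <- function(X) {
  dm <- dim(X); Tn <- dm[2]; To <- Tn %/% 2L
  X1 <- X[, 2L * seq_len(To) - 1L, , , drop = FALSE]
  X2 <- X[, 2L * seq_len(To), , , drop = FALSE]
  mask <- X1 >= X2
  list(Y = X1 * mask + X2 * !mask,
       cache = list(mask = mask, Tn = Tn, dims = dm))
}

maxpool2_bw <- function(dY, cache) {
  dm <- cache$dims; To <- dm[2] %/% 2L
  dX <- array(0, dm)
  dX[, 2L * seq_len(To) - 1L, , ] <- dY * cache$mask
  dX[, 2L * seq_len(To), , ] <- dY * !cache$mask
  dX
}

# ---- parameter containers -------------------------------------------------

init_lstm_trunk <- function(params, prefix, input_dim, units) {
  p <- lstm_init(input_dim, units)
  params[[paste0(prefix, ".Wx")]] <- p$Wx
  params[[paste0(prefix, ".Wh")]] <- p$Wh
  params[[paste0(prefix, ".b")]] <- p$b
  params
}

init_conv_trunk <- function(params, spec) {
  D <- spec$input_dim
  kset <- list(conv2d = c(18L, 1L, 1L, 32L),
               conv2d_1 = c(9L, 1L, 32L, 64L),
               conv2d_2 = c(3L, 1L, 64L, 128L),
               conv2d_3 = c(1L, D, 128L, 128L))
  for (nm in names(kset)) {
    kk <- kset[[nm]]
    fan_in <- kk[1] * kk[2] * kk[3]; fan_out <- kk[1] * kk[2] * kk[4]
    params[[paste0(nm, ".W")]] <-
      glorot_uniform(kk[1] * kk[2] * kk[3], kk[4], fan_in, fan_out)
    params[[paste0(nm, ".b")]] <- rep(0, kk[4])
  }
  params
}

lstm_units <- function(spec, which = 1L) {
  ls <- Filter(function(l) l$kind == "LSTM", spec$layers)
  ls[[which]]$units
}

# Initialize all trainable parameters (and batch-norm running state) for a
# model specification. Deterministic given the RNG state.
init_params <- function(spec) {
  params <- list(); state <- list()
  u <- if (spec$name != "CNN") lstm_units(spec, 1L) else NULL
  flat <- NULL
  if (spec$name %in% c("CNN", "LSTM_CNN")) {
    tl <- Filter(function(l) l$kind == "Flatten", spec$layers)
    flat <- tl[[1]]$output_shape
  }
  switch(spec$name,
    S_LSTM = {
      params <- init_lstm_trunk(params, "lstm", spec$input_dim, u)
      params$`batch_normalization.gamma` <- rep(1, u)
      params$`batch_normalization.beta` <- rep(0, u)
      state$batch_normalization <- list(mean = rep(0, u), var = rep(1, u))
      params$`dense.W` <- glorot_uniform(u, spec$n_classes)
      params$`dense.b` <- rep(0, spec$n_classes)
    },
    D_LSTM = {
      u2 <- lstm_units(spec, 2L)
      params <- init_lstm_trunk(params, "lstm", spec$input_dim, u)
      params <- init_lstm_trunk(params, "lstm_1", u, u2)
      params$`batch_normalization.gamma` <- rep(1, u2)
      params$`batch_normalization.beta` <- rep(0, u2)
      state$batch_normalization <- list(mean = rep(0, u2), var = rep(1, u2))
      params$`dense.W` <- glorot_uniform(u2, spec$n_classes)
      params$`dense.b` <- rep(0, spec$n_classes)
    },
    CNN = {
      params <- init_conv_trunk(params, spec)
      params$`dense.W` <- glorot_uniform(flat, spec$n_classes)
      params$`dense.b` <- rep(0, spec$n_classes)
    },
    LSTM_ATTN = {
      params <- init_lstm_trunk(params, "lstm", spec$input_dim, u)
      params$`attention_score_vec.W` <- glorot_uniform(u, u)
      params$`attention_vector.W` <- glorot_uniform(2L * u, u)
      params$`dense.W` <- glorot_uniform(u, spec$n_classes)
      params$`dense.b` <- rep(0, spec$n_classes)
    },
    LSTM_CNN = {
      params <- init_lstm_trunk(params, "lstm", spec$input_dim, u)
      params$`batch_normalization.gamma` <- rep(1, u)
      params$`batch_normalization.beta` <- rep(0, u)
      state$batch_normalization <- list(mean = rep(0, u), var = rep(1, u))
      params <- init_conv_trunk(params, spec)
      params$`dense.W` <- glorot_uniform(u + flat, spec$n_classes)
      params$`dense.b` <- rep(0, spec$n_classes)
    },
    stop_invalid("unknown model name: ", spec$name))
  list(params = params, state = state)
}

# Number of trainable scalars in a parameter container; must equal
# total_parameters() of the corresponding spec.
engine_parameter_count <- function(params) {
  sum(vapply(params, length, 1L))
}

# ---- per-architecture features --------------------------------------------

cnn_trunk_fw <- function(params, X3, dropout_rate = 0, training = FALSE) {
  dm <- dim(X3)
  X <- array(X3, c(dm, 1L))               # B x T x W x 1
  c1 <- conv_time_fw(X, params$`conv2d.W`, params$`conv2d.b`,
                     stride = 2L, padding = "same")
  p1 <- maxpool2_fw(c1$Y)
  c2 <- conv_time_fw(p1$Y, params$`conv2d_1.W`, params$`conv2d_1.b`)
  c3 <- conv_time_fw(c2$Y, params$`conv2d_2.W`, params$`conv2d_2.b`)
  p2 <- maxpool2_fw(c3$Y)
  c4 <- conv_width_fw(p2$Y, params$`conv2d_3.W`, params$`conv2d_3.b`)
  dmo <- dim(c4$Y)
  feats <- matrix(c4$Y, dmo[1], prod(dmo[-1]))
  list(feats = feats,
       cache = list(c1 = c1$cache, p1 = p1$cache, c2 = c2$cache,
                    c3 = c3$cache, p2 = p2$cache, c4 = c4$cache,
                    out_dim = dmo))
}

cnn_trunk_bw <- function(params, cache, dfeats) {
  dY <- array(dfeats, cache$out_dim)
  g4 <- conv_width_bw(dY, params$`conv2d_3.W`, cache$c4)
  dP2 <- maxpool2_bw(g4$dX, cache$p2)
  g3 <- conv_time_bw(dP2, params$`conv2d_2.W`, cache$c3)
  g2 <- conv_time_bw(g3$dX, params$`conv2d_1.W`, cache$c2)
  dP1 <- maxpool2_bw(g2$dX, cache$p1)
  g1 <- conv_time_bw(dP1, params$`conv2d.W`, cache$c1, want_dx = FALSE)
  list(grads = list(`conv2d.W` = g1$dW, `conv2d.b` = g1$db,
                    `conv2d_1.W` = g2$dW, `conv2d_1.b` = g2$db,
                    `conv2d_2.W` = g3$dW, `conv2d_2.b` = g3$db,
                    `conv2d_3.W` = g4$dW, `conv2d_3.b` = g4$db))
}

# Forward pass to the classifier head. Returns probabilities, per-layer
# caches and (possibly updated) batch-norm state.
nn_forward <- function(spec, params, state, X, training = FALSE) {
  dr <- if (training) spec$dropout_rate else 0
  cache <- list()
  feats <- NULL
  if (spec$name == "CNN") {
    tr <- cnn_trunk_fw(params, X)
    feats <- tr$feats; cache$cnn <- tr$cache
  } else if (spec$name == "S_LSTM") {
    l <- lstm_fw(X, list(Wx = params$`lstm.Wx`, Wh = params$`lstm.Wh`,
                         b = params$`lstm.b`))
    bn <- batchnorm_fw(l$h_last, params$`batch_normalization.gamma`,
                       params$`batch_normalization.beta`,
                       state$batch_normalization, training)
    state$batch_normalization <- bn$state
    dp <- dropout_fw(bn$Y, dr, training)
    feats <- dp$Y
    cache$lstm <- l$cache; cache$bn <- bn$cache; cache$dp <- dp$mask
  } else if (spec$name == "D_LSTM") {
    l1 <- lstm_fw(X, list(Wx = params$`lstm.Wx`, Wh = params$`lstm.Wh`,
                          b = params$`lstm.b`), return_sequences = TRUE)
    d1 <- dropout_fw(l1$H, dr, training)
    l2 <- lstm_fw(d1$Y, list(Wx = params$`lstm_1.Wx`,
                             Wh = params$`lstm_1.Wh`,
                             b = params$`lstm_1.b`))
    bn <- batchnorm_fw(l2$h_last, params$`batch_normalization.gamma`,
                       params$`batch_normalization.beta`,
                       state$batch_normalization, training)
    state$batch_normalization <- bn$state
    d2 <- dropout_fw(bn$Y, dr, training)
    feats <- d2$Y
    cache$lstm <- l1$cache; cache$d1 <- d1$mask
    cache$lstm_1 <- l2$cache; cache$bn <- bn$cache; cache$d2 <- d2$mask
  } else if (spec$name == "LSTM_ATTN") {
    l <- lstm_fw(X, list(Wx = params$`lstm.Wx`, Wh = params$`lstm.Wh`,
                         b = params$`lstm.b`), return_sequences = TRUE)
    dp <- dropout_fw(l$H, dr, training)
    H <- dp$Y
    dmh <- dim(H); B <- dmh[1]; Tn <- dmh[2]; u <- dmh[3]
    q <- slice_t(H, Tn)
    Hm <- matrix(H, B * Tn, u)
    P <- Hm %*% params$`attention_score_vec.W`
    qrep <- q[rep(seq_len(B), Tn), , drop = FALSE]
    scores <- matrix(rowSums(P * qrep) / sqrt(u), B, Tn)
    alpha <- softmax_rows(scores)
    ctx <- matrix(0, B, u)
    for (t in seq_len(Tn)) ctx <- ctx + slice_t(H, t) * alpha[, t]
    conc <- cbind(ctx, q)
    av <- tanh(conc %*% params$`attention_vector.W`)
    feats <- av
    cache$lstm <- l$cache; cache$dp <- dp$mask
    cache$attn <- list(H = H, Hm = Hm, P = P, q = q, alpha = alpha,
                       conc = conc, av = av, B = B, Tn = Tn, u = u)
  } else if (spec$name == "LSTM_CNN") {
    l <- lstm_fw(X, list(Wx = params$`lstm.Wx`, Wh = params$`lstm.Wh`,
                         b = params$`lstm.b`))
    bn <- batchnorm_fw(l$h_last, params$`batch_normalization.gamma`,
                       params$`batch_normalization.beta`,
                       state$batch_normalization, training)
    state$batch_normalization <- bn$state
    dp <- dropout_fw(bn$Y, dr, training)
    tr <- cnn_trunk_fw(params, X)
    feats <- cbind(dp$Y, tr$feats)
    cache$lstm <- l$cache; cache$bn <- bn$cache; cache$dp <- dp$mask
    cache$cnn <- tr$cache
    cache$u <- ncol(dp$Y)
  } else stop_invalid("unknown model name: ", spec$name)

  hd <- dense_fw(feats, params$`dense.W`, params$`dense.b`)
  probs <- softmax_rows(hd$Y)
  cache$head <- hd$cache
  list(probs = probs, cache = cache, state = state)
}

# Backward pass from the head-logit gradient; returns named gradients.
nn_backward <- function(spec, params, cache, dlogits) {
  gh <- dense_bw(dlogits, params$`dense.W`, cache$head)
  grads <- list(`dense.W` = gh$dW, `dense.b` = gh$db)
  dfeats <- gh$dX
  if (spec$name == "CNN") {
    grads <- c(grads, cnn_trunk_bw(params, cache$cnn, dfeats)$grads)
  } else if (spec$name %in% c("S_LSTM", "LSTM_CNN")) {
    if (spec$name == "LSTM_CNN") {
      u <- cache$u
      dlstm_feats <- dfeats[, seq_len(u), drop = FALSE]
      dcnn_feats <- dfeats[, -seq_len(u), drop = FALSE]
      grads <- c(grads, cnn_trunk_bw(params, cache$cnn, dcnn_feats)$grads)
    } else dlstm_feats <- dfeats
    d1 <- dropout_bw(dlstm_feats, cache$dp)
    gb <- batchnorm_bw(d1, params$`batch_normalization.gamma`, cache$bn)
    grads$`batch_normalization.gamma` <- gb$dgamma
    grads$`batch_normalization.beta` <- gb$dbeta
    gl <- lstm_bw(list(Wx = params$`lstm.Wx`, Wh = params$`lstm.Wh`,
                       b = params$`lstm.b`), cache$lstm,
                  dh_last = gb$dX)
    grads$`lstm.Wx` <- gl$dWx; grads$`lstm.Wh` <- gl$dWh
    grads$`lstm.b` <- gl$db
  } else if (spec$name == "D_LSTM") {
    d2 <- dropout_bw(dfeats, cache$d2)
    gb <- batchnorm_bw(d2, params$`batch_normalization.gamma`, cache$bn)
    grads$`batch_normalization.gamma` <- gb$dgamma
    grads$`batch_normalization.beta` <- gb$dbeta
    g2 <- lstm_bw(list(Wx = params$`lstm_1.Wx`, Wh = params$`lstm_1.Wh`,
                       b = params$`lstm_1.b`), cache$lstm_1,
                  dh_last = gb$dX, want_dx = TRUE)
    grads$`lstm_1.Wx` <- g2$dWx; grads$`lstm_1.Wh` <- g2$dWh
    grads$`lstm_1.b` <- g2$db
    dH1 <- dropout_bw(g2$dX, cache$d1)
    g1 <- lstm_bw(list(Wx = params$`lstm.Wx`, Wh = params$`lstm.Wh`,
                       b = params$`lstm.b`), cache$lstm, dH = dH1)
    grads$`lstm.Wx` <- g1$dWx; grads$`lstm.Wh` <- g1$dWh
    grads$`lstm.b` <- g1$db
  } else if (spec$name == "LSTM_ATTN") {
    at <- cache$attn
    B <- at$B; Tn <- at$Tn; u <- at$u
    dav <- dfeats * (1 - at$av^2)
    grads$`attention_vector.W` <- crossprod(at$conc, dav)
    dconc <- tcrossprod(dav, params$`attention_vector.W`)
    dctx <- dconc[, seq_len(u), drop = FALSE]
    dq <- dconc[, u + seq_len(u), drop = FALSE]
    # context = sum_t alpha_t * H_t
    dalpha <- matrix(0, B, Tn)
    dH <- array(0, c(B, Tn, u))
    for (t in seq_len(Tn)) {
      dalpha[, t] <- rowSums(dctx * slice_t(at$H, t))
      dH[, t, ] <- dctx * at$alpha[, t]
    }
    # softmax over time steps
    dscores <- at$alpha * (dalpha - rowSums(dalpha * at$alpha))
    # scores = (P . q) / sqrt(u)
    sc <- as.numeric(dscores) / sqrt(u)          # (B*Tn), sample-fastest
    qrep <- at$q[rep(seq_len(B), Tn), , drop = FALSE]
    dP <- qrep * sc
    P3 <- array(at$P, c(B, Tn, u))
    for (t in seq_len(Tn))
      dq <- dq + slice_t(P3, t) * (dscores[, t] / sqrt(u))
    grads$`attention_score_vec.W` <- crossprod(at$Hm, dP)
    dHm <- tcrossprod(dP, params$`attention_score_vec.W`)
    dH <- dH + array(dHm, c(B, Tn, u))
    dH[, Tn, ] <- dH[, Tn, ] + dq
    dHdrop <- dropout_bw(dH, cache$dp)
    gl <- lstm_bw(list(Wx = params$`lstm.Wx`, Wh = params$`lstm.Wh`,
                       b = params$`lstm.b`), cache$lstm, dH = dHdrop)
    grads$`lstm.Wx` <- gl$dWx; grads$`lstm.Wh` <- gl$dWh
    grads$`lstm.b` <- gl$db
  }
  grads
}

# Regularization terms used by all models: L2 on the head kernel, plus an
# L2 activity penalty on the softmax output for the plain LSTM heads.
head_regularizers <- function(spec) {
  dense <- spec$layers[[length(spec$layers)]]
  list(l2 = if (is.null(dense$l2)) 0 else dense$l2,
       activity_l2 = if (is.null(dense$activity_l2)) 0
       else dense$activity_l2)
}

# Loss (cross-entropy + regularization) and gradients for one batch.
# `rng_seed` fixes the dropout masks, making the value reproducible.
nn_loss_and_grads <- function(spec, params, state, X, Y, training = TRUE,
                              rng_seed = NULL, want_grads = TRUE) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  fw <- nn_forward(spec, params, state, X, training = training)
  B <- nrow(Y)
  reg <- head_regularizers(spec)
  loss <- cross_entropy(Y, fw$probs) +
    reg$l2 * sum(params$`dense.W`^2)
  if (reg$activity_l2 > 0)
    loss <- loss + reg$activity_l2 * sum(fw$probs^2) / B
  out <- list(loss = loss, probs = fw$probs, state = fw$state)
  if (!want_grads) return(out)
  dlogits <- (fw$probs - Y) / B
  if (reg$activity_l2 > 0) {
    g <- 2 * reg$activity_l2 * fw$probs / B
    dlogits <- dlogits + fw$probs * (g - rowSums(g * fw$probs))
  }
  grads <- nn_backward(spec, params, fw$cache, dlogits)
  grads$`dense.W` <- grads$`dense.W` + 2 * reg$l2 * params$`dense.W`
  out$grads <- grads
  out
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / corr1) / (sqrt(opt$v[[nm]] / corr2) + eps)
  }
  list(params = params, opt = opt)
}
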