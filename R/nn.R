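# Native neural-network engine: window-shared 2D convolution blocks, masked
# LSTM recurrence and a dense softmax head, with reverse-mode gradients and
# Adam. All feature maps live as 2D matrices (rows = images, columns =
# column-major (height, width, channel) positions); convolution and pooling
# use flat column-index gathers precomputed once per geometry, so the hot
# path is plain BLAS GEMM plus fast 2D indexing. Validated against central
# finite differences in the test suite.

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

glorot_uniform <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

## ---- activations -----------------------------------------------------------

act_forward <- function(x, kind) {
  if (kind == "ReLU") {
    return(pmax(x, 0))
  }
  neg <- x < 0
  y <- x
  if (kind == "ELU") {
    y[neg] <- expm1(x[neg])
  } else if (kind == "LReLU") {
    y[neg] <- 0.3 * x[neg]
  } else {
    stop("unknown activation: ", kind)
  }
  y
}

# y = act_forward(x, kind) is cheaper to differentiate than x for ELU
act_backward <- function(dy, x, y, kind) {
  neg <- x < 0
  d <- dy
  if (kind == "ReLU") {
    d[neg] <- 0
  } else if (kind == "ELU") {
    d[neg] <- dy[neg] * (y[neg] + 1)
  } else if (kind == "LReLU") {
    d[neg] <- dy[neg] * 0.3
  } else {
    stop("unknown activation: ", kind)
  }
  d
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- geometry (precomputed flat column indices) ----------------------------

conv_pad_sizes <- function(k) c(floor((k - 1) / 2), ceiling((k - 1) / 2))

# column indices for "same"-padded stride-1 convolution over an (h, w, cin)
# feature block; offset blocks are ordered kernel-row fastest, then kernel
# column, channel fastest within a block matching aperm(W, c(3, 1, 2, 4))
conv_geom <- function(h, w, cin, kernel) {
  kh <- kernel[1]
  kw <- kernel[2]
  ph <- conv_pad_sizes(kh)
  pw <- conv_pad_sizes(kw)
  hp <- h + kh - 1L
  wp <- w + kw - 1L
  hh <- rep(seq_len(h), times = w * cin)
  ww <- rep(rep(seq_len(w), each = h), times = cin)
  cc <- rep(seq_len(cin), each = h * w)
  off_idx <- function(i, j) (i + hh - 1L) + hp * (j + ww - 2L) + hp * wp * (cc - 1L)
  blocks <- vector("list", kh * kw)
  k <- 0L
  for (j in seq_len(kw)) {
    for (i in seq_len(kh)) {
      k <- k + 1L
      blocks[[k]] <- off_idx(i, j)
    }
  }
  list(
    h = h, w = w, cin = cin, kh = kh, kw = kw,
    pad_cols = hp * wp * cin,
    interior = off_idx(ph[1] + 1L, pw[1] + 1L),
    big_idx = unlist(blocks),
    blocks = blocks,
    block_len = h * w * cin,
    k_dim = kh * kw * cin
  )
}

# pool size requested (2,2); an axis shorter than 2 is not pooled
pool_sizes <- function(h, w, pool = c(2L, 2L)) {
  c(if (h < pool[1]) 1L else pool[1], if (w < pool[2]) 1L else pool[2])
}

pool_geom <- function(h, w, cin, pool) {
  ph <- pool[1]
  pw <- pool[2]
  h_out <- h %/% ph
  w_out <- w %/% pw
  hh <- rep(seq_len(h_out), times = w_out * cin)
  ww <- rep(rep(seq_len(w_out), each = h_out), times = cin)
  cc <- rep(seq_len(cin), each = h_out * w_out)
  cand <- vector("list", ph * pw)
  k <- 0L
  for (b in seq_len(pw)) {
    for (a in seq_len(ph)) {
      k <- k + 1L
      cand[[k]] <- (a + ph * (hh - 1L)) + h * (b + pw * (ww - 1L) - 1L) + h * w * (cc - 1L)
    }
  }
  list(
    h_out = h_out, w_out = w_out, cin = cin, in_cols = h * w * cin,
    out_cols = h_out * w_out * cin, cand = cand
  )
}

## ---- 2D convolution, stride 1, "same" padding ------------------------------

conv_w_mat <- function(W) {
  d <- dim(W) # (kh, kw, cin, cout)
  matrix(aperm(W, c(3L, 1L, 2L, 4L)), d[1] * d[2] * d[3], d[4])
}

conv_w_unmat <- function(dW_mat, d) {
  aperm(array(dW_mat, c(d[3], d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
}

# A: (M, h*w*cin) matrix. Returns out (M, h*w*cout).
conv2d_forward <- function(A, W, b, geom) {
  m <- nrow(A)
  Ap <- matrix(0, m, geom$pad_cols)
  Ap[, geom$interior] <- A
  col <- Ap[, geom$big_idx]
  n_pos <- m * geom$h * geom$w
  dim(col) <- c(n_pos, geom$k_dim)
  Y <- col %*% conv_w_mat(W) + rep(b, each = n_pos)
  cout <- dim(W)[4]
  dim(Y) <- c(m, geom$h * geom$w * cout)
  list(out = Y, cache = list(Ap = Ap, m = m))
}

conv2d_backward <- function(dY, W, geom, cache) {
  m <- cache$m
  n_pos <- m * geom$h * geom$w
  cout <- dim(W)[4]
  dim(dY) <- c(n_pos, cout)
  col <- cache$Ap[, geom$big_idx]
  dim(col) <- c(n_pos, geom$k_dim)
  w_mat <- conv_w_mat(W)
  dW <- conv_w_unmat(crossprod(col, dY), dim(W))
  db <- colSums(dY)
  dcol <- dY %*% t(w_mat)
  dim(dcol) <- c(m, geom$block_len * length(geom$blocks))
  dAp <- matrix(0, m, geom$pad_cols)
  for (k in seq_along(geom$blocks)) {
    cols_k <- (k - 1L) * geom$block_len + seq_len(geom$block_len)
    idx <- geom$blocks[[k]]
    dAp[, idx] <- dAp[, idx] + dcol[, cols_k]
  }
  list(dA = dAp[, geom$interior], dW = dW, db = db)
}

## ---- max pooling, non-overlapping, clipped pool window ---------------------

maxpool_forward <- function(A, geom) {
  m <- nrow(A)
  p <- length(geom$cand)
  if (p == 1L) {
    return(list(out = A, cache = NULL))
  }
  n <- m * geom$out_cols
  cand <- matrix(0, n, p)
  for (k in seq_len(p)) cand[, k] <- A[, geom$cand[[k]]]
  idx <- max.col(cand, ties.method = "first")
  out <- cand[cbind(seq_len(n), idx)]
  dim(out) <- c(m, geom$out_cols)
  list(out = out, cache = idx)
}

maxpool_backward <- function(dY, geom, cache) {
  m <- nrow(dY)
  if (is.null(cache)) {
    return(dY)
  }
  dA <- matrix(0, m, geom$in_cols)
  dvec <- as.vector(dY)
  for (k in seq_along(geom$cand)) {
    contrib <- dvec * (cache == k)
    dim(contrib) <- c(m, geom$out_cols)
    dA[, geom$cand[[k]]] <- contrib
  }
  dA
}

## ---- regularizers ----------------------------------------------------------

dropout_forward <- function(A, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = A, cache = NULL))
  }
  keep <- 1 - rate
  mask <- matrix((stats::runif(length(A)) < keep) / keep, nrow(A))
  list(out = A * mask, cache = mask)
}

dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

# A: (M, spatial*cn); statistics per channel over rows and spatial positions
batchnorm_forward <- function(A, spatial, gamma, beta, run_mean, run_var, training) {
  m <- nrow(A)
  cn <- length(gamma)
  n_pos <- m * spatial
  Am <- A
  dim(Am) <- c(n_pos, cn)
  if (training) {
    mu <- colMeans(Am)
    xc <- Am - rep(mu, each = n_pos)
    v <- colMeans(xc^2)
    new_mean <- BN_MOMENTUM * run_mean + (1 - BN_MOMENTUM) * mu
    new_var <- BN_MOMENTUM * run_var + (1 - BN_MOMENTUM) * v
  } else {
    xc <- Am - rep(run_mean, each = n_pos)
    v <- run_var
    new_mean <- run_mean
    new_var <- run_var
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(inv_sd, each = n_pos)
  Y <- xhat * rep(gamma, each = n_pos) + rep(beta, each = n_pos)
  dim(Y) <- c(m, spatial * cn)
  list(
    out = Y,
    cache = list(xhat = xhat, inv_sd = inv_sd, n_pos = n_pos, training = training),
    run_mean = new_mean, run_var = new_var
  )
}

batchnorm_backward <- function(dY, gamma, cache) {
  m <- nrow(dY)
  n_pos <- cache$n_pos
  cn <- length(gamma)
  dYm <- dY
  dim(dYm) <- c(n_pos, cn)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * rep(gamma, each = n_pos)
  if (cache$training) {
    dA <- rep(cache$inv_sd, each = n_pos) *
      (dxhat - rep(colMeans(dxhat), each = n_pos) -
        cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n_pos))
  } else {
    dA <- dxhat * rep(cache$inv_sd, each = n_pos)
  }
  dim(dA) <- c(m, ncol(dY))
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

## ---- masked LSTM -----------------------------------------------------------

# Xin: (N*X, F) with rows of time step t at (t-1)*N + 1:N; mask: (N, X).
# Masked steps leave hidden and cell state untouched (the recurrence skips
# all-padding windows), so appending masked windows never changes the output.
lstm_forward <- function(Xin, mask, Wx, Wh, b, n, x_steps) {
  units <- ncol(Wh) %/% 4L
  Xproj <- Xin %*% Wx + rep(b, each = nrow(Xin))
  h <- matrix(0, n, units)
  cc <- matrix(0, n, units)
  H <- matrix(0, nrow(Xin), units)
  caches <- vector("list", x_steps)
  ii <- seq_len(units)
  for (t in seq_len(x_steps)) {
    rows_t <- (t - 1L) * n + seq_len(n)
    z <- Xproj[rows_t, , drop = FALSE] + h %*% Wh
    gi <- sigmoid(z[, ii, drop = FALSE])
    gf <- sigmoid(z[, units + ii, drop = FALSE])
    gg <- tanh(z[, 2L * units + ii, drop = FALSE])
    go <- sigmoid(z[, 3L * units + ii, drop = FALSE])
    c_new <- gf * cc + gi * gg
    tanh_c <- tanh(c_new)
    h_new <- go * tanh_c
    m <- as.numeric(mask[, t])
    caches[[t]] <- list(
      i = gi, f = gf, g = gg, o = go, tanh_c = tanh_c,
      c_prev = cc, h_prev = h, m = m
    )
    h <- h_new * m + h * (1 - m)
    cc <- c_new * m + cc * (1 - m)
    H[rows_t, ] <- h
  }
  list(H = H, h_last = h, caches = caches, Xin = Xin)
}

# dH: per-step gradient on the (post-mask) hidden states, (N*X, units) or NULL;
# dh_last: gradient on the final hidden state, (N, units) or NULL.
lstm_backward <- function(fwd, mask, Wx, Wh, dH = NULL, dh_last = NULL) {
  caches <- fwd$caches
  x_steps <- length(caches)
  n <- length(caches[[1]]$m)
  units <- ncol(fwd$h_last)
  tWx <- t(Wx)
  tWh <- t(Wh)
  dWx <- array(0, dim(Wx))
  dWh <- array(0, dim(Wh))
  db <- numeric(4L * units)
  dXin <- matrix(0, nrow(fwd$Xin), ncol(fwd$Xin))
  dh <- if (is.null(dh_last)) matrix(0, n, units) else dh_last
  dc <- matrix(0, n, units)
  for (t in rev(seq_len(x_steps))) {
    rows_t <- (t - 1L) * n + seq_len(n)
    if (!is.null(dH)) dh <- dh + dH[rows_t, , drop = FALSE]
    cc <- caches[[t]]
    m <- cc$m
    dh_new <- dh * m
    dh_carry <- dh * (1 - m)
    dc_new <- dc * m
    dc_carry <- dc * (1 - m)
    do_ <- dh_new * cc$tanh_c
    dc_new <- dc_new + dh_new * cc$o * (1 - cc$tanh_c^2)
    df <- dc_new * cc$c_prev
    di <- dc_new * cc$g
    dg <- dc_new * cc$i
    dc <- dc_new * cc$f + dc_carry
    dz <- cbind(
      di * cc$i * (1 - cc$i),
      df * cc$f * (1 - cc$f),
      dg * (1 - cc$g^2),
      do_ * cc$o * (1 - cc$o)
    )
    dXin[rows_t, ] <- dz %*% tWx
    dWx <- dWx + crossprod(fwd$Xin[rows_t, , drop = FALSE], dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dh <- dz %*% tWh + dh_carry
  }
  list(dXin = dXin, dWx = dWx, dWh = dWh, db = db)
}

## ---- dense / softmax -------------------------------------------------------

dense_forward <- function(X, W, b) {
  list(out = X %*% W + rep(b, each = nrow(X)), cache = X)
}

dense_backward <- function(dY, W, cache) {
  list(dX = dY %*% t(W), dW = crossprod(cache, dY), db = colSums(dY))
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# categorical cross-entropy; y_onehot (N, K). Returns loss and dlogits.
cross_entropy_softmax <- function(logits, y_onehot) {
  p <- softmax(logits)
  eps <- 1e-12
  loss <- -mean(rowSums(y_onehot * log(p + eps)))
  list(loss = loss, probs = p, dlogits = (p - y_onehot) / nrow(logits))
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}
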