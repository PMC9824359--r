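ACTIVATIONS <- c("ReLU", "ELU", "LReLU")
VARIANTS <- c("baseline", "imu_centric", "channel_centric")
SCHEMES <- c("fixed_kernel", "decreasing_kernel")
REGULARIZERS <- c("dropout_0.2", "batch_norm")
BATCH_SIZES <- c(4L, 8L, 16L, 32L)

#' CNN-LSTM architecture configuration
#'
#' Captures the tunable hyperparameters of the scoring network together with
#' its fixed constants: 256 units in every LSTM layer, dense layers of
#' 512 / 128 / 3 neurons, softmax output, tanh LSTM activation with sigmoid
#' recurrent activation, Glorot-uniform initialization, Adam with learning
#' rate 0.0001 and categorical cross-entropy loss. The convolutional front
#' end comes in three variants: `baseline` (one stacked channels-by-time
#' image, square kernels), `imu_centric` (one convolutional branch per IMU,
#' `(1, 5)` kernels, branch outputs concatenated before the recurrence) and
#' `channel_centric` (stacked image but `(1, 5)` time-axis kernels shared
#' across channels).
#'
#' @param variant `"baseline"`, `"imu_centric"` or `"channel_centric"`.
#' @param n_blocks number of CNN-blocks, 1..3.
#' @param scheme filter/kernel scheme: `"fixed_kernel"` (16/32/64 filters,
#'   5x5 kernels) or `"decreasing_kernel"` (16/32/64 filters, 9x9 / 5x5 /
#'   3x3 kernels). Ignored for the kernel shape of the non-baseline variants,
#'   which always use `(1, 5)`.
#' @param activation `"ReLU"`, `"ELU"` or `"LReLU"` — used in every layer
#'   except the LSTM layers and the softmax output.
#' @param regularizer `"dropout_0.2"` or `"batch_norm"`, closing each
#'   CNN-block after max-pooling.
#' @param n_lstm_layers 1 or 2.
#' @param batch_size one of 4, 8, 16, 32.
#' @param seed seed for weight initialization.
#' @return object of class `architecture_config`.
#' @export
architecture_config <- function(variant = "baseline", n_blocks = 3L,
                                scheme = "fixed_kernel", activation = "ELU",
                                regularizer = "dropout_0.2", n_lstm_layers = 2L,
                                batch_size = 32L, seed = 1L) {
  variant <- match.arg(variant, VARIANTS)
  scheme <- match.arg(scheme, SCHEMES)
  activation <- match.arg(activation, ACTIVATIONS)
  regularizer <- match.arg(regularizer, REGULARIZERS)
  if (!n_blocks %in% 1:3) stop("`n_blocks` must be 1, 2 or 3", call. = FALSE)
  if (!n_lstm_layers %in% 1:2) stop("`n_lstm_layers` must be 1 or 2", call. = FALSE)
  if (!batch_size %in% BATCH_SIZES) stop("`batch_size` must be one of 4/8/16/32", call. = FALSE)
  structure(
    list(
      variant = variant,
      n_blocks = as.integer(n_blocks),
      scheme = scheme,
      activation = activation,
      regularizer = regularizer,
      n_lstm_layers = as.integer(n_lstm_layers),
      batch_size = as.integer(batch_size),
      lstm_units = 256L,
      dense_units = c(512L, 128L, 3L),
      output_activation = "softmax",
      lstm_activation = "tanh",
      lstm_recurrent_activation = "sigmoid",
      weight_init = "glorot_uniform",
      learning_rate = 1e-4,
      loss = "categorical_crossentropy",
      seed = as.integer(seed)
    ),
    class = "architecture_config"
  )
}

#' @export
print.architecture_config <- function(x, ...) {
  cat(sprintf(
    "<architecture_config> %s | %d CNN-block(s), %s, %s, %s | %d LSTM layer(s) x %d | dense %s | batch %d\n",
    x$variant, x$n_blocks, x$scheme, x$activation, x$regularizer,
    x$n_lstm_layers, x$lstm_units, paste(x$dense_units, collapse = "/"), x$batch_size
  ))
  invisible(x)
}

#' Resolve the CNN-block stack of a configuration
#'
#' Filters always increase per block (first `n_blocks` of 16/32/64). Kernels
#' depend on scheme and variant: the baseline variant uses square kernels —
#' 5x5 throughout under `fixed_kernel`, or 9x9 / 5x5 / 3x3 under
#' `decreasing_kernel` — while the IMU-centric and channel-centric variants
#' convolve along the time axis only with a `(1, 5)` kernel in every block,
#' regardless of scheme.
#'
#' @param scheme `"fixed_kernel"` or `"decreasing_kernel"`.
#' @param n_blocks 1..3.
#' @param variant network variant (see [architecture_config()]).
#' @param regularizer block regularizer (recorded on each block spec).
#' @return list of `n_blocks` block specs with fields `n_filters`, `kernel`,
#'   `pool` (requested, `(2, 2)` with axis clipping at build time) and
#'   `regularizer`.
#' @export
resolve_blocks <- function(scheme, n_blocks, variant, regularizer = "dropout_0.2") {
  scheme <- match.arg(scheme, SCHEMES)
  variant <- match.arg(variant, VARIANTS)
  regularizer <- match.arg(regularizer, REGULARIZERS)
  if (!n_blocks %in% 1:3) stop("`n_blocks` must be in 1..3", call. = FALSE)
  filters <- c(16L, 32L, 64L)[seq_len(n_blocks)]
  kernels <- if (variant == "baseline") {
    switch(scheme,
      fixed_kernel = rep(list(c(5L, 5L)), n_blocks),
      decreasing_kernel = list(c(9L, 9L), c(5L, 5L), c(3L, 3L))[seq_len(n_blocks)]
    )
  } else {
    rep(list(c(1L, 5L)), n_blocks)
  }
  lapply(seq_len(n_blocks), function(i) {
    list(
      n_filters = filters[i], kernel = kernels[[i]],
      pool = c(2L, 2L), regularizer = regularizer
    )
  })
}

# walk a block stack over an input image (h, w), returning per-block shapes
# (with the clipped pool sizes actually applied) and precomputed gather
# geometries for the convolution and pooling index tricks
plan_branch <- function(blocks, h, w) {
  cin <- 1L
  plan <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    bl <- blocks[[i]]
    pool <- pool_sizes(h, w, bl$pool)
    h_out <- h %/% pool[1]
    w_out <- w %/% pool[2]
    if (h_out < 1L || w_out < 1L) {
      stop("input too small to survive the pooling stack (minimal admissible window length is 1)",
        call. = FALSE
      )
    }
    plan[[i]] <- list(
      n_filters = bl$n_filters, kernel = bl$kernel, pool = pool,
      regularizer = bl$regularizer, cin = cin,
      in_shape = c(h, w), out_shape = c(h_out, w_out),
      conv_geom = conv_geom(h, w, cin, bl$kernel),
      pool_geom = pool_geom(h, w, bl$n_filters, pool)
    )
    cin <- bl$n_filters
    h <- h_out
    w <- w_out
  }
  list(blocks = plan, feat_dim = h * w * cin)
}

#' Build a CNN-LSTM scoring network
#'
#' Instantiates one of the three variants on a windowed input of shape
#' `(X, C, W)` (windows, channel rows, window length). Every window is
#' processed by the same CNN-block stack (weights shared across windows); for
#' the IMU-centric variant each IMU owns its own stack and the per-window
#' branch outputs are concatenated. The window sequence then passes the
#' masked recurrence (`n_lstm_layers` LSTM layers of 256 units; all-padding
#' windows are skipped) and the dense 512 / 128 / 3 softmax head.
#' Convolutions use "same" spatial padding; pooling is `(2, 2)` with an axis
#' skipped once it is shorter than 2. Weights are Glorot-uniform, seeded.
#'
#' @param config an [architecture_config()].
#' @param input_shape integer vector `(X, C, W)`.
#' @param layout the [imu_layout()] (required for `imu_centric` branch
#'   partitioning).
#' @return object of class `imuqc_model`.
#' @export
build_model <- function(config, input_shape, layout = NULL) {
  stopifnot(inherits(config, "architecture_config"))
  if (length(input_shape) != 3L) stop("`input_shape` must be (X, C, W)", call. = FALSE)
  x_windows <- as.integer(input_shape[1])
  n_rows <- as.integer(input_shape[2])
  w_len <- as.integer(input_shape[3])
  if (w_len < 1L) stop("window length must be >= 1", call. = FALSE)
  blocks <- resolve_blocks(config$scheme, config$n_blocks, config$variant, config$regularizer)

  branches <- if (config$variant == "imu_centric") {
    if (is.null(layout)) stop("imu_centric variant requires `layout`", call. = FALSE)
    if (n_channel_rows(layout) != n_rows) {
      stop("input_shape channel rows do not match layout", call. = FALSE)
    }
    lapply(seq_len(layout$n_imus) - 1L, function(k) {
      list(
        name = sprintf("imu%02d", k + 1L),
        rows = imu_rows(layout, k),
        plan = plan_branch(blocks, layout$channels_per_imu, w_len)
      )
    })
  } else {
    list(list(name = "stack", rows = seq_len(n_rows), plan = plan_branch(blocks, n_rows, w_len)))
  }

  feat_dim <- sum(vapply(branches, function(b) b$plan$feat_dim, numeric(1)))

  params <- list()
  state <- list()
  with_seed(derive_seed(config$seed, "init"), {
    for (b in branches) {
      for (i in seq_along(b$plan$blocks)) {
        bl <- b$plan$blocks[[i]]
        kh <- bl$kernel[1]; kw <- bl$kernel[2]
        tag <- sprintf("%s_conv%d", b$name, i)
        params[[paste0(tag, "_W")]] <- glorot_uniform(
          kh * kw * bl$cin, kh * kw * bl$n_filters, c(kh, kw, bl$cin, bl$n_filters)
        )
        params[[paste0(tag, "_b")]] <- numeric(bl$n_filters)
        if (bl$regularizer == "batch_norm") {
          bn <- sprintf("%s_bn%d", b$name, i)
          params[[paste0(bn, "_gamma")]] <- rep(1, bl$n_filters)
          params[[paste0(bn, "_beta")]] <- numeric(bl$n_filters)
          state[[paste0(bn, "_mean")]] <- numeric(bl$n_filters)
          state[[paste0(bn, "_var")]] <- rep(1, bl$n_filters)
        }
      }
    }
    fin <- feat_dim
    for (l in seq_len(config$n_lstm_layers)) {
      u <- config$lstm_units
      params[[sprintf("lstm%d_Wx", l)]] <- glorot_uniform(fin, 4L * u, c(fin, 4L * u))
      params[[sprintf("lstm%d_Wh", l)]] <- glorot_uniform(u, 4L * u, c(u, 4L * u))
      bvec <- numeric(4L * u)
      bvec[u + seq_len(u)] <- 1 # unit forget-gate bias
      params[[sprintf("lstm%d_b", l)]] <- bvec
      fin <- u
    }
    for (l in seq_along(config$dense_units)) {
      fout <- config$dense_units[l]
      params[[sprintf("dense%d_W", l)]] <- glorot_uniform(fin, fout, c(fin, fout))
      params[[sprintf("dense%d_b", l)]] <- numeric(fout)
      fin <- fout
    }
  })

  structure(
    list(
      config = config, input_shape = c(x_windows, n_rows, w_len),
      branches = branches, feat_dim = feat_dim,
      params = params, state = state, n_classes = 3L
    ),
    class = "imuqc_model"
  )
}

#' @export
print.imuqc_model <- function(x, ...) {
  inv <- describe_model(x)
  cat(sprintf(
    "<imuqc_model> %s, input (X=%d, C=%d, W=%d), %d branches, %s parameters\n",
    x$config$variant, x$input_shape[1], x$input_shape[2], x$input_shape[3],
    length(x$branches), format(sum(inv$n_params), big.mark = ",")
  ))
  invisible(x)
}

## ---- full-model forward / backward ----------------------------------------

branch_forward <- function(branch, params, state, A, config, training) {
  caches <- vector("list", length(branch$plan$blocks))
  state_updates <- list()
  for (i in seq_along(branch$plan$blocks)) {
    bl <- branch$plan$blocks[[i]]
    tag <- sprintf("%s_conv%d", branch$name, i)
    cv <- conv2d_forward(A, params[[paste0(tag, "_W")]], params[[paste0(tag, "_b")]],
      bl$conv_geom)
    pre_act <- cv$out
    A <- act_forward(pre_act, config$activation)
    post_act <- A
    pl <- maxpool_forward(A, bl$pool_geom)
    A <- pl$out
    if (bl$regularizer == "dropout_0.2") {
      dp <- dropout_forward(A, 0.2, training)
      A <- dp$out
      reg_cache <- dp$cache
    } else {
      bn <- sprintf("%s_bn%d", branch$name, i)
      bf <- batchnorm_forward(
        A, prod(bl$out_shape),
        params[[paste0(bn, "_gamma")]], params[[paste0(bn, "_beta")]],
        state[[paste0(bn, "_mean")]], state[[paste0(bn, "_var")]], training
      )
      A <- bf$out
      reg_cache <- bf$cache
      state_updates[[paste0(bn, "_mean")]] <- bf$run_mean
      state_updates[[paste0(bn, "_var")]] <- bf$run_var
    }
    caches[[i]] <- list(
      conv = cv$cache, pre_act = pre_act, post_act = post_act,
      pool = pl$cache, reg = reg_cache
    )
  }
  list(out = A, caches = caches, state_updates = state_updates)
}

branch_backward <- function(branch, params, dA, caches, config) {
  grads <- list()
  for (i in rev(seq_along(branch$plan$blocks))) {
    bl <- branch$plan$blocks[[i]]
    tag <- sprintf("%s_conv%d", branch$name, i)
    ch <- caches[[i]]
    if (bl$regularizer == "dropout_0.2") {
      dA <- dropout_backward(dA, ch$reg)
    } else {
      bn <- sprintf("%s_bn%d", branch$name, i)
      bb <- batchnorm_backward(dA, params[[paste0(bn, "_gamma")]], ch$reg)
      dA <- bb$dA
      grads[[paste0(bn, "_gamma")]] <- bb$dgamma
      grads[[paste0(bn, "_beta")]] <- bb$dbeta
    }
    dA <- maxpool_backward(dA, bl$pool_geom, ch$pool)
    dA <- act_backward(dA, ch$pre_act, ch$post_act, config$activation)
    cb <- conv2d_backward(dA, params[[paste0(tag, "_W")]], bl$conv_geom, ch$conv)
    grads[[paste0(tag, "_W")]] <- cb$dW
    grads[[paste0(tag, "_b")]] <- cb$db
    dA <- cb$dA
  }
  grads
}

# x: (N, X, C, W); mask: (N, X) logical
model_forward <- function(model, x, mask, training = FALSE) {
  cfg <- model$config
  d <- dim(x)
  n <- d[1]
  x_steps <- d[2]
  m_img <- n * x_steps
  feats <- matrix(0, m_img, model$feat_dim)
  br_caches <- vector("list", length(model$branches))
  state_updates <- list()
  col0 <- 0L
  for (bi in seq_along(model$branches)) {
    br <- model$branches[[bi]]
    A <- x[, , br$rows, , drop = FALSE]
    dim(A) <- c(m_img, length(br$rows) * d[4])
    bf <- branch_forward(br, model$params, model$state, A, cfg, training)
    fdim <- br$plan$feat_dim
    feats[, col0 + seq_len(fdim)] <- bf$out
    br_caches[[bi]] <- bf$caches
    state_updates <- c(state_updates, bf$state_updates)
    col0 <- col0 + fdim
  }

  lstm_caches <- vector("list", cfg$n_lstm_layers)
  seq_in <- feats
  for (l in seq_len(cfg$n_lstm_layers)) {
    lf <- lstm_forward(
      seq_in, mask,
      model$params[[sprintf("lstm%d_Wx", l)]],
      model$params[[sprintf("lstm%d_Wh", l)]],
      model$params[[sprintf("lstm%d_b", l)]],
      n, x_steps
    )
    lstm_caches[[l]] <- lf
    seq_in <- lf$H
  }
  h <- lstm_caches[[cfg$n_lstm_layers]]$h_last

  dense_caches <- vector("list", length(cfg$dense_units))
  for (l in seq_along(cfg$dense_units)) {
    df <- dense_forward(h, model$params[[sprintf("dense%d_W", l)]],
      model$params[[sprintf("dense%d_b", l)]])
    pre <- df$out
    h <- if (l < length(cfg$dense_units)) act_forward(pre, cfg$activation) else pre
    dense_caches[[l]] <- list(x = df$cache, pre = pre, post = h)
  }

  list(
    logits = h, probs = softmax(h),
    cache = list(
      branches = br_caches, lstm = lstm_caches, dense = dense_caches,
      n = n, x_steps = x_steps, d = d, mask = mask
    ),
    state_updates = state_updates
  )
}

model_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  grads <- list()
  dh <- dlogits
  for (l in rev(seq_along(cfg$dense_units))) {
    ch <- fwd$cache$dense[[l]]
    db_ <- dense_backward(dh, model$params[[sprintf("dense%d_W", l)]], ch$x)
    grads[[sprintf("dense%d_W", l)]] <- db_$dW
    grads[[sprintf("dense%d_b", l)]] <- db_$db
    dh <- db_$dX
    if (l > 1L) {
      prev <- fwd$cache$dense[[l - 1L]]
      dh <- act_backward(dh, prev$pre, prev$post, cfg$activation)
    }
  }

  dH <- NULL
  dh_last <- dh
  for (l in rev(seq_len(cfg$n_lstm_layers))) {
    lf <- fwd$cache$lstm[[l]]
    lb <- lstm_backward(
      lf, fwd$cache$mask,
      model$params[[sprintf("lstm%d_Wx", l)]],
      model$params[[sprintf("lstm%d_Wh", l)]],
      dH = dH, dh_last = dh_last
    )
    grads[[sprintf("lstm%d_Wx", l)]] <- lb$dWx
    grads[[sprintf("lstm%d_Wh", l)]] <- lb$dWh
    grads[[sprintf("lstm%d_b", l)]] <- lb$db
    dH <- lb$dXin
    dh_last <- NULL
  }

  col0 <- 0L
  for (bi in seq_along(model$branches)) {
    br <- model$branches[[bi]]
    fdim <- br$plan$feat_dim
    dA <- dH[, col0 + seq_len(fdim), drop = FALSE]
    bg <- branch_backward(br, model$params, dA, fwd$cache$branches[[bi]], cfg)
    grads <- c(grads, bg)
    col0 <- col0 + fdim
  }
  grads
}

#' Predict class probabilities for preprocessed repetitions
#'
#' @param model a trained [build_model()] network.
#' @param x input array `(N, X, C, W)` from [preprocess_batch()].
#' @param mask `N x X` logical validity mask.
#' @param chunk_size evaluation batch size bounding memory use (default 64).
#' @return `N x 3` matrix of class probabilities (columns = scores 1, 2, 3;
#'   rows sum to 1).
#' @export
predict_proba <- function(model, x, mask, chunk_size = 64L) {
  stopifnot(inherits(model, "imuqc_model"))
  n <- dim(x)[1]
  out <- matrix(0, n, model$n_classes)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    fw <- model_forward(model,
      x[idx, , , , drop = FALSE], mask[idx, , drop = FALSE],
      training = FALSE
    )
    out[idx, ] <- fw$probs
  }
  out
}

#' Predict quality scores (1/2/3) for preprocessed repetitions
#'
#' @inheritParams predict_proba
#' @return integer vector of predicted scores.
#' @export
predict_scores <- function(model, x, mask, chunk_size = 64L) {
  probs <- predict_proba(model, x, mask, chunk_size)
  as.integer(max.col(probs, ties.method = "first"))
}

#' Layer inventory of a model
#'
#' Deterministic structural summary (independent of weight values): one row
#' per layer with its output shape and trainable parameter count.
#'
#' @param model a [build_model()] result.
#' @return data.frame with columns `layer`, `type`, `output_shape`,
#'   `n_params`.
#' @export
describe_model <- function(model) {
  stopifnot(inherits(model, "imuqc_model"))
  cfg <- model$config
  rows <- list()
  add <- function(layer, type, shape, n_params) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer, type = type, output_shape = shape, n_params = n_params,
      stringsAsFactors = FALSE
    )
  }
  x_steps <- model$input_shape[1]
  for (br in model$branches) {
    for (i in seq_along(br$plan$blocks)) {
      bl <- br$plan$blocks[[i]]
      tag <- sprintf("%s_conv%d", br$name, i)
      add(
        tag, "conv2d_shared",
        sprintf("(X=%d, %d, %d, %d)", x_steps, bl$in_shape[1], bl$in_shape[2], bl$n_filters),
        prod(bl$kernel) * bl$cin * bl$n_filters + bl$n_filters
      )
      add(
        sprintf("%s_pool%d", br$name, i), "maxpool",
        sprintf("(X=%d, %d, %d, %d)", x_steps, bl$out_shape[1], bl$out_shape[2], bl$n_filters),
        0L
      )
      if (bl$regularizer == "dropout_0.2") {
        add(sprintf("%s_dropout%d", br$name, i), "dropout(0.2)",
          sprintf("(X=%d, %d, %d, %d)", x_steps, bl$out_shape[1], bl$out_shape[2], bl$n_filters),
          0L
        )
      } else {
        add(sprintf("%s_bn%d", br$name, i), "batch_norm",
          sprintf("(X=%d, %d, %d, %d)", x_steps, bl$out_shape[1], bl$out_shape[2], bl$n_filters),
          2L * bl$n_filters
        )
      }
    }
  }
  add("concat_mask", "masking", sprintf("(X=%d, %d)", x_steps, model$feat_dim), 0L)
  fin <- model$feat_dim
  for (l in seq_len(cfg$n_lstm_layers)) {
    u <- cfg$lstm_units
    add(sprintf("lstm%d", l), sprintf("lstm(%d units)", u),
      sprintf("(X=%d, %d)", x_steps, u), 4L * u * (fin + u + 1L)
    )
    fin <- u
  }
  for (l in seq_along(cfg$dense_units)) {
    fout <- cfg$dense_units[l]
    type <- if (l == length(cfg$dense_units)) "dense_softmax" else sprintf("dense_%s", cfg$activation)
    add(sprintf("dense%d", l), type, sprintf("(%d)", fout), fin * fout + fout)
    fin <- fout
  }
  do.call(rbind, rows)
}
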