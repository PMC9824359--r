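test_that("resolve_blocks reproduces the printed block schemes", {
  b <- resolve_blocks("fixed_kernel", 3, "baseline")
  expect_equal(vapply(b, function(x) x$n_filters, integer(1)), c(16L, 32L, 64L))
  expect_true(all(vapply(b, function(x) identical(x$kernel, c(5L, 5L)), logical(1))))

  b2 <- resolve_blocks("decreasing_kernel", 3, "baseline")
  expect_equal(lapply(b2, `[[`, "kernel"), list(c(9L, 9L), c(5L, 5L), c(3L, 3L)))

  b3 <- resolve_blocks("fixed_kernel", 2, "channel_centric")
  expect_equal(vapply(b3, function(x) x$n_filters, integer(1)), c(16L, 32L))
  expect_true(all(vapply(b3, function(x) identical(x$kernel, c(1L, 5L)), logical(1))))
  # kernel (1, 5) regardless of scheme for the non-baseline variants
  b4 <- resolve_blocks("decreasing_kernel", 3, "imu_centric")
  expect_true(all(vapply(b4, function(x) identical(x$kernel, c(1L, 5L)), logical(1))))

  expect_error(resolve_blocks("fixed_kernel", 4, "baseline"), "1..3")
})

test_that("architecture_config fixes the non-tunable constants", {
  cfg <- architecture_config()
  expect_identical(cfg$lstm_units, 256L)
  expect_identical(cfg$dense_units, c(512L, 128L, 3L))
  expect_identical(cfg$learning_rate, 1e-4)
  expect_identical(cfg$output_activation, "softmax")
  expect_identical(cfg$weight_init, "glorot_uniform")
  expect_error(architecture_config(batch_size = 7), "4/8/16/32")
  expect_error(architecture_config(n_blocks = 0), "1, 2 or 3")
})

test_that("describe_model reports the fixed layer inventory", {
  model <- build_model(headline_config(1), c(10, 102, 12), imu_layout())
  inv <- describe_model(model)
  lstm_rows <- inv[grepl("^lstm", inv$layer), ]
  expect_identical(nrow(lstm_rows), 2L)
  expect_true(all(grepl("256 units", lstm_rows$type)))
  dense_rows <- inv[grepl("^dense", inv$layer), ]
  expect_identical(dense_rows$output_shape, c("(512)", "(128)", "(3)"))
  conv_rows <- inv[inv$type == "conv2d_shared", ]
  expect_match(conv_rows$output_shape[1], "16")
  expect_match(conv_rows$output_shape[2], "32")
  expect_match(conv_rows$output_shape[3], "64")
  # structure is independent of the initialization seed
  inv2 <- describe_model(build_model(headline_config(99), c(10, 102, 12), imu_layout()))
  expect_identical(inv2, inv)
})

test_that("the IMU-centric model has exactly one convolutional branch per IMU", {
  cfg <- tiny_arch(variant = "imu_centric", n_blocks = 1, seed = 2)
  model <- build_model(cfg, c(4, 102, 8), imu_layout())
  expect_length(model$branches, 17L)
  inv <- describe_model(model)
  expect_identical(sum(inv$type == "conv2d_shared"), 17L)
  # branch rows partition the 102 channel rows
  rows <- sort(unlist(lapply(model$branches, `[[`, "rows")))
  expect_identical(rows, 1:102)
})

test_that("channel_centric differs from baseline only by kernel shape", {
  shape <- c(4, 12, 8)
  layout <- tiny_layout()
  cc <- build_model(tiny_arch(variant = "channel_centric", seed = 3), shape, layout)
  base <- build_model(tiny_arch(variant = "baseline", seed = 3), shape, layout)
  inv_cc <- describe_model(cc)
  inv_base <- describe_model(base)
  expect_identical(inv_cc$layer, inv_base$layer)
  expect_identical(inv_cc$output_shape, inv_base$output_shape)
  # forcing the baseline kernel onto the channel-centric builder makes the
  # inventories identical, parameter counts included
  cc_forced <- cc
  for (i in seq_along(cc_forced$branches[[1]]$plan$blocks)) {
    cc_forced$branches[[1]]$plan$blocks[[i]]$kernel <- c(5L, 5L)
  }
  expect_identical(describe_model(cc_forced), inv_base)
})

test_that("model outputs are probabilities and padding windows never change them", {
  set.seed(14)
  layout <- tiny_layout()
  model <- build_model(tiny_arch(seed = 6), c(4, 12, 8), layout)
  x <- array(rnorm(3 * 4 * 12 * 8), c(3, 4, 12, 8))
  mask <- matrix(TRUE, 3, 4)
  p <- predict_proba(model, x, mask)
  expect_equal(rowSums(p), rep(1, 3))
  expect_true(all(p >= 0))

  # appending all-zero masked windows leaves class probabilities unchanged
  x2 <- array(0, c(3, 7, 12, 8))
  x2[, 1:4, , ] <- x
  mask2 <- cbind(mask, FALSE, FALSE, FALSE)
  p2 <- predict_proba(model, x2, mask2)
  expect_lt(max(abs(p2 - p)), 1e-5)

  # permuting two all-zero masked trailing windows changes nothing
  x3 <- x2[, c(1:4, 6, 5, 7), , , drop = FALSE]
  p3 <- predict_proba(model, x3, mask2)
  expect_lt(max(abs(p3 - p)), 1e-6)
})

test_that("the shared convolution matches a naive direct convolution", {
  set.seed(19)
  for (kern in list(c(5L, 5L), c(1L, 5L), c(3L, 3L), c(9L, 9L))) {
    h <- 12L; w <- 10L; cin <- 2L; cout <- 3L; M <- 2L
    A4 <- array(rnorm(M * h * w * cin), c(M, h, w, cin))
    W <- array(rnorm(prod(kern) * cin * cout), c(kern, cin, cout))
    b <- rnorm(cout)
    Am <- A4
    dim(Am) <- c(M, h * w * cin)
    out <- conv2d_forward(Am, W, b, conv_geom(h, w, cin, kern))$out
    ref <- oracle_conv2d(A4, W, b)
    dim(ref) <- c(M, h * w * cout)
    expect_lt(max(abs(out - ref)), 1e-10)
  }
})

test_that("analytic gradients match central finite differences", {
  # smooth configuration (ELU + batch normalization): dropout is stochastic
  # and ReLU/LReLU kinks break finite differences
  set.seed(42)
  layout <- tiny_layout()
  cfg <- tiny_arch(
    n_blocks = 2, scheme = "decreasing_kernel", activation = "ELU",
    regularizer = "batch_norm", n_lstm_layers = 2, seed = 3
  )
  model <- build_model(cfg, c(4, 12, 8), layout)
  N <- 3
  x <- array(rnorm(N * 4 * 12 * 8), c(N, 4, 12, 8))
  mask <- matrix(TRUE, N, 4)
  mask[2, 4] <- FALSE
  x[2, 4, , ] <- 0
  y <- one_hot(c(1L, 3L, 2L))
  loss_fn <- function(m) {
    cross_entropy_softmax(model_forward(m, x, mask, training = TRUE)$logits, y)$loss
  }
  fw <- model_forward(model, x, mask, training = TRUE)
  ce <- cross_entropy_softmax(fw$logits, y)
  grads <- model_backward(model, fw, ce$dlogits)
  eps <- 1e-6
  for (nm in names(grads)) {
    g <- grads[[nm]]
    for (ii in sample(length(g), min(3, length(g)))) {
      m2 <- model
      m2$params[[nm]][ii] <- m2$params[[nm]][ii] + eps
      m3 <- model
      m3$params[[nm]][ii] <- m3$params[[nm]][ii] - eps
      num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
      expect_lt(
        abs(num - g[ii]) / max(1e-6, abs(num) + abs(g[ii])),
        1e-3
      )
    }
  }
})

test_that("build_model validates shapes", {
  expect_error(build_model(tiny_arch(), c(4, 12), tiny_layout()), "X, C, W")
  expect_error(
    build_model(tiny_arch(variant = "imu_centric"), c(4, 12, 8)),
    "requires `layout`"
  )
  expect_error(
    build_model(tiny_arch(variant = "imu_centric"), c(4, 13, 8), tiny_layout()),
    "do not match layout"
  )
})
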