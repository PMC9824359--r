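#' Stack the channels of a repetition into its 2D network representation
#'
#' Returns the channels-by-time matrix in layout order (accelerometer x/y/z
#' then gyroscope x/y/z, IMU by IMU) after verifying the row count against the
#' layout. Repetition matrices are already stored in this arrangement, so the
#' operation is a validated identity.
#'
#' @param rep a [repetition()].
#' @param layout the [imu_layout()].
#' @return numeric matrix with `n_channel_rows(layout)` rows.
#' @export
stack_channels <- function(rep, layout) {
  stopifnot(inherits(rep, "repetition"), inherits(layout, "imu_layout"))
  if (nrow(rep$data) != n_channel_rows(layout)) {
    stop(sprintf(
      "repetition '%s' has %d rows, layout requires %d",
      rep$repetition_id, nrow(rep$data), n_channel_rows(layout)
    ), call. = FALSE)
  }
  rep$data
}

#' Fit per-modality standardization parameters
#'
#' Pools all accelerometer channels (all IMUs, axes and time steps) of the
#' fitting repetitions into one sample and all gyroscope channels into
#' another, and records the mean and standard deviation of each pool.
#' Standardization is separate per modality but shared across channels, which
#' preserves relative axis amplitudes. Fit on training folds only so no test
#' information leaks into the representation.
#'
#' @param reps list of [repetition()] objects (a training split).
#' @param layout the [imu_layout()].
#' @return object of class `standardization_params` with fields `accel_mean`,
#'   `accel_sd`, `gyro_mean`, `gyro_sd`.
#' @export
fit_standardization <- function(reps, layout) {
  stopifnot(length(reps) > 0L, inherits(layout, "imu_layout"))
  acc <- accel_rows(layout)
  gyr <- gyro_rows(layout)
  accel_pool <- unlist(lapply(reps, function(r) as.vector(r$data[acc, , drop = FALSE])))
  gyro_pool <- unlist(lapply(reps, function(r) as.vector(r$data[gyr, , drop = FALSE])))
  # population (1/n) spread, matching the usual scaler convention
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  p <- list(
    accel_mean = mean(accel_pool), accel_sd = sd_pop(accel_pool),
    gyro_mean = mean(gyro_pool), gyro_sd = sd_pop(gyro_pool)
  )
  if (p$accel_sd <= 0 || p$gyro_sd <= 0) {
    stop("cannot standardize a constant channel pool (zero variance)", call. = FALSE)
  }
  class(p) <- "standardization_params"
  p
}

#' Apply standardization to a stacked repetition matrix
#'
#' @param mat channels-by-time matrix in layout order.
#' @param params a [fit_standardization()] result.
#' @param layout the [imu_layout()].
#' @return the standardized matrix.
#' @export
apply_standardization <- function(mat, params, layout) {
  stopifnot(inherits(params, "standardization_params"), inherits(layout, "imu_layout"))
  acc <- accel_rows(layout)
  gyr <- gyro_rows(layout)
  mat[acc, ] <- (mat[acc, , drop = FALSE] - params$accel_mean) / params$accel_sd
  mat[gyr, ] <- (mat[gyr, , drop = FALSE] - params$gyro_mean) / params$gyro_sd
  mat
}

#' Windowing configuration for the network input representation
#'
#' Every repetition is zero-padded to `pad_length` samples and cut into
#' `n_windows` equal, non-overlapping windows of width
#' `W = pad_length / n_windows`. The default pad length is the longest
#' repetition of the fitting set rounded up to a multiple of `n_windows`.
#'
#' @param n_windows number of windows X (default 10).
#' @param pad_length padded length L in samples; must be a multiple of
#'   `n_windows`, with `L / n_windows >= 8`. If `NULL`, fit with
#'   [fit_pad_length()].
#' @return object of class `windowing_config`.
#' @export
windowing_config <- function(n_windows = 10L, pad_length = NULL) {
  stop_if_not_count(n_windows, "n_windows")
  cfg <- list(n_windows = as.integer(n_windows), pad_length = NULL, window_length = NULL)
  class(cfg) <- "windowing_config"
  if (!is.null(pad_length)) cfg <- set_pad_length(cfg, pad_length)
  cfg
}

#' Set the pad length of a windowing configuration explicitly
#'
#' @param config a [windowing_config()].
#' @param pad_length padded length L; must be a multiple of the window count
#'   with a resulting window width of at least 8 samples.
#' @return the completed `windowing_config`.
#' @export
set_pad_length <- function(config, pad_length) {
  stop_if_not_count(pad_length, "pad_length")
  pad_length <- as.integer(pad_length)
  if (pad_length %% config$n_windows != 0L) {
    stop("`pad_length` must be a multiple of `n_windows`", call. = FALSE)
  }
  w <- pad_length %/% config$n_windows
  if (w < 8L) {
    stop(sprintf("window length %d < 8; increase pad_length or reduce n_windows", w),
      call. = FALSE
    )
  }
  config$pad_length <- pad_length
  config$window_length <- w
  config
}

#' Fit the pad length of a windowing configuration from training repetitions
#'
#' Sets L to the maximum repetition length of `reps`, rounded up to a
#' multiple of `n_windows` (and to a minimum window width of 8 samples).
#'
#' @param config a [windowing_config()].
#' @param reps list of [repetition()] objects (training split only).
#' @return the completed `windowing_config`.
#' @export
fit_pad_length <- function(config, reps) {
  stopifnot(inherits(config, "windowing_config"), length(reps) > 0L)
  t_max <- max(vapply(reps, function(r) ncol(r$data), integer(1)))
  x <- config$n_windows
  L <- max(ceiling(t_max / x), 8L) * x
  set_pad_length(config, L)
}

#' Zero-pad and window a repetition matrix
#'
#' Pads the matrix with exact-zero columns up to `pad_length`, cuts it into
#' `n_windows` equal windows, and records a per-window validity mask: a
#' window is valid when it overlaps the recorded samples `1..T`; all-padding
#' windows are masked out and later skipped by the recurrent stage.
#' Standardize before padding, so padding stays exactly zero.
#'
#' @param mat channels-by-time matrix (C x T).
#' @param config a completed [windowing_config()].
#' @return object of class `windowed_input`: list with `x` (array
#'   `(X, C, W)`), `mask` (logical X), and `t_real` (T). Concatenating the
#'   windows along time reproduces the padded matrix; together with `t_real`
#'   the original matrix is recovered exactly.
#' @export
pad_and_window <- function(mat, config) {
  stopifnot(inherits(config, "windowing_config"))
  if (is.null(config$pad_length)) {
    stop("windowing_config has no pad_length; call fit_pad_length() first", call. = FALSE)
  }
  t_real <- ncol(mat)
  L <- config$pad_length
  if (t_real > L) {
    stop(sprintf(
      "repetition exceeds pad length: T = %d > L = %d", t_real, L
    ), call. = FALSE)
  }
  X <- config$n_windows
  W <- config$window_length
  C <- nrow(mat)
  padded <- matrix(0, C, L)
  padded[, seq_len(t_real)] <- mat
  x <- array(0, dim = c(X, C, W))
  for (w in seq_len(X)) {
    x[w, , ] <- padded[, ((w - 1L) * W + 1L):(w * W)]
  }
  mask <- (seq_len(X) - 1L) * W + 1L <= t_real
  structure(list(x = x, mask = mask, t_real = t_real), class = "windowed_input")
}

#' Reconstruct the original matrix from a windowed input
#'
#' @param wi a [pad_and_window()] result.
#' @return the un-padded C x T matrix.
#' @export
unwindow <- function(wi) {
  stopifnot(inherits(wi, "windowed_input"))
  d <- dim(wi$x)
  C <- d[2]
  W <- d[3]
  padded <- matrix(0, C, d[1] * W)
  for (w in seq_len(d[1])) {
    padded[, ((w - 1L) * W + 1L):(w * W)] <- wi$x[w, , ]
  }
  padded[, seq_len(wi$t_real), drop = FALSE]
}

#' Build per-IMU windowed inputs
#'
#' Splits the stacked representation by IMU for the IMU-centric network
#' variant: one `(X, 6, W)` windowed input per IMU, all sharing the mask of
#' the full stacked matrix (padding is common to all IMUs).
#'
#' @param mat standardized channels-by-time matrix.
#' @param config a completed [windowing_config()].
#' @param layout the [imu_layout()].
#' @return list of `n_imus` `windowed_input` objects, in layout order.
#' @export
build_per_imu_inputs <- function(mat, config, layout) {
  stopifnot(inherits(layout, "imu_layout"))
  base <- pad_and_window(mat, config)
  lapply(seq_len(layout$n_imus) - 1L, function(k) {
    rows <- imu_rows(layout, k)
    structure(
      list(x = base$x[, rows, , drop = FALSE], mask = base$mask, t_real = base$t_real),
      class = "windowed_input"
    )
  })
}

#' Preprocess a set of repetitions into a network-ready batch
#'
#' Standardizes (per modality), zero-pads, windows and masks every
#' repetition, returning dense arrays ready for [build_model()] /
#' [train_network()]. Parameters (`params`, `config`) must have been fitted
#' on a training split.
#'
#' @param reps list of [repetition()] objects.
#' @param params a [fit_standardization()] result.
#' @param config a completed [windowing_config()].
#' @param layout the [imu_layout()].
#' @return list with `x` (array `(N, X, C, W)`), `mask` (N x X logical
#'   matrix), `labels` (integer vector, `NA` where unresolved) and `t_real`.
#' @export
preprocess_batch <- function(reps, params, config, layout) {
  stopifnot(length(reps) > 0L)
  wis <- lapply(reps, function(r) {
    pad_and_window(apply_standardization(stack_channels(r, layout), params, layout), config)
  })
  N <- length(wis)
  d <- dim(wis[[1]]$x)
  x <- array(0, dim = c(N, d))
  mask <- matrix(FALSE, N, d[1])
  for (i in seq_len(N)) {
    x[i, , , ] <- wis[[i]]$x
    mask[i, ] <- wis[[i]]$mask
  }
  labels <- unname(vapply(reps, function(r) as.integer(r$resolved_label), integer(1)))
  list(
    x = x, mask = mask, labels = labels,
    t_real = unname(vapply(wis, function(w) w$t_real, integer(1)))
  )
}
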