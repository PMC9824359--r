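#' Channel layout of a body-worn IMU network
#'
#' Describes how the channels of a multi-IMU recording are stacked into the
#' rows of a repetition matrix. Channels are sorted IMU by IMU; within one IMU
#' the three accelerometer axes (x, y, z, in g) come first, followed by the
#' three gyroscope axes (x, y, z, in degrees/s). The row holding channel `c`
#' (0-based, 0..5) of IMU `k` (0-based) is therefore `6 * k + c` (0-based),
#' i.e. row `6 * k + c + 1` in R's 1-based indexing.
#'
#' The default layout is the 17-segment full-body configuration used by
#' commercial inertial motion-capture suits (pelvis, sternum, head, plus
#' shoulder, upper arm, forearm, hand, upper leg, lower leg and foot on both
#' sides), sampled at 120 Hz.
#'
#' @param n_imus number of IMUs (default 17).
#' @param imu_order character vector of segment names, length `n_imus`;
#'   defaults to the full-body segment set for 17 IMUs or generic names
#'   otherwise.
#' @return an object of class `imu_layout`.
#' @export
imu_layout <- function(n_imus = 17L, imu_order = NULL) {
  stop_if_not_count(n_imus, "n_imus")
  n_imus <- as.integer(n_imus)
  if (is.null(imu_order)) {
    imu_order <- if (n_imus == 17L) default_segments_17() else paste0("imu", seq_len(n_imus))
  }
  if (length(imu_order) != n_imus || anyDuplicated(imu_order)) {
    stop("`imu_order` must contain one unique name per IMU", call. = FALSE)
  }
  structure(
    list(
      n_imus = n_imus,
      channels_per_imu = 6L,
      imu_order = as.character(imu_order),
      channel_order = c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
    ),
    class = "imu_layout"
  )
}

default_segments_17 <- function() {
  c(
    "pelvis", "sternum", "head",
    "right_shoulder", "right_upper_arm", "right_forearm", "right_hand",
    "left_shoulder", "left_upper_arm", "left_forearm", "left_hand",
    "right_upper_leg", "right_lower_leg", "right_foot",
    "left_upper_leg", "left_lower_leg", "left_foot"
  )
}

#' Total number of channel rows of a layout
#' @param layout an `imu_layout`.
#' @return integer, `n_imus * channels_per_imu`.
#' @export
n_channel_rows <- function(layout) {
  stopifnot(inherits(layout, "imu_layout"))
  layout$n_imus * layout$channels_per_imu
}

#' Row index of one channel of one IMU
#'
#' @param layout an `imu_layout`.
#' @param imu 0-based IMU index (0..n_imus-1).
#' @param channel 0-based channel index within the IMU (0..5; 0-2 accel x/y/z,
#'   3-5 gyro x/y/z).
#' @return 1-based row index into the repetition matrix, `6 * imu + channel + 1`.
#' @export
channel_row <- function(layout, imu, channel) {
  stopifnot(inherits(layout, "imu_layout"))
  if (any(imu < 0 | imu >= layout$n_imus)) stop("IMU index out of range", call. = FALSE)
  if (any(channel < 0 | channel >= layout$channels_per_imu)) {
    stop("channel index out of range", call. = FALSE)
  }
  as.integer(layout$channels_per_imu * imu + channel + 1L)
}

# 1-based row indices of all accelerometer (resp. gyroscope) channels
accel_rows <- function(layout) {
  k <- rep(seq_len(layout$n_imus) - 1L, each = 3L)
  c_idx <- rep(0:2, times = layout$n_imus)
  channel_row(layout, k, c_idx)
}

gyro_rows <- function(layout) {
  k <- rep(seq_len(layout$n_imus) - 1L, each = 3L)
  c_idx <- rep(3:5, times = layout$n_imus)
  channel_row(layout, k, c_idx)
}

# rows of IMU k (0-based): 6k+1 .. 6k+6
imu_rows <- function(layout, imu) {
  channel_row(layout, rep(imu, 6L), 0:5)
}

#' @export
print.imu_layout <- function(x, ...) {
  cat(sprintf(
    "<imu_layout> %d IMUs x %d channels = %d rows\n",
    x$n_imus, x$channels_per_imu, n_channel_rows(x)
  ))
  invisible(x)
}

#' @export
format.imu_layout <- function(x, ...) {
  sprintf("imu_layout(%d x %d)", x$n_imus, x$channels_per_imu)
}
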