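ROTATION_TOL <- 1e-9

#' Validate a rotation matrix
#'
#' @param R a 3x3 numeric matrix.
#' @param tol orthonormality / determinant tolerance (default 1e-9).
#' @return `TRUE` if `R` is orthonormal with determinant +1 within `tol`.
#' @export
is_rotation <- function(R, tol = ROTATION_TOL) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && is.numeric(R) &&
    max(abs(crossprod(R) - diag(3))) <= tol &&
    abs(det(R) - 1) <= tol
}

assert_rotation <- function(R, name) {
  if (!is_rotation(R)) {
    stop(sprintf("`%s` is not a valid rotation matrix (orthonormal, det +1)", name),
      call. = FALSE
    )
  }
  invisible(R)
}

#' Compose the IMU-to-body-segment rotation
#'
#' Given the marker-derived orientation of the IMU in the camera frame, of the
#' room in the camera frame, and of the body segment in the room frame,
#' returns the rotation mapping IMU coordinates into segment coordinates:
#' \deqn{R_{imu \to seg} = R_{seg \to room}^{-1} \, R_{room \to cam}^{-1} \, R_{imu \to cam}.}
#' The convention throughout is that `R_a_to_b` maps coordinates expressed in
#' frame `a` to frame `b`; inverses are transposes since inputs are rotations.
#'
#' @param r_imu_to_cam,r_room_to_cam,r_segment_to_room 3x3 rotation matrices.
#' @return the 3x3 rotation `R_imu_to_segment`.
#' @export
sensor_to_segment <- function(r_imu_to_cam, r_room_to_cam, r_segment_to_room) {
  assert_rotation(r_imu_to_cam, "r_imu_to_cam")
  assert_rotation(r_room_to_cam, "r_room_to_cam")
  assert_rotation(r_segment_to_room, "r_segment_to_room")
  t(r_segment_to_room) %*% t(r_room_to_cam) %*% r_imu_to_cam
}

#' Rotate a repetition's triaxial data into segment frames
#'
#' Applies one rotation per IMU to both the accelerometer and the gyroscope
#' triplet of that IMU at every time step (`v -> R v`), so that all subjects
#' share segment coordinate frames. Metadata are unchanged; per-sample vector
#' norms are preserved by construction.
#'
#' @param rep a [repetition()].
#' @param rotations list of 3x3 rotation matrices, one per IMU, in layout
#'   order.
#' @param layout the repetition's [imu_layout()].
#' @return the aligned [repetition()].
#' @export
apply_alignment <- function(rep, rotations, layout) {
  stopifnot(inherits(rep, "repetition"), inherits(layout, "imu_layout"))
  if (length(rotations) != layout$n_imus) {
    stop(sprintf(
      "need one rotation per IMU: got %d for %d IMUs",
      length(rotations), layout$n_imus
    ), call. = FALSE)
  }
  out <- rep$data
  for (k in seq_len(layout$n_imus) - 1L) {
    R <- rotations[[k + 1L]]
    assert_rotation(R, sprintf("rotations[[%d]]", k + 1L))
    acc <- channel_row(layout, rep(k, 3L), 0:2)
    gyr <- channel_row(layout, rep(k, 3L), 3:5)
    out[acc, ] <- R %*% rep$data[acc, , drop = FALSE]
    out[gyr, ] <- R %*% rep$data[gyr, , drop = FALSE]
  }
  rep$data <- out
  rep
}

#' Load per-IMU rotation sets from a JSON file
#'
#' Expected schema: a JSON object mapping subject ids to objects mapping IMU
#' segment names to 9-element row-major 3x3 rotation matrices.
#'
#' @param file path to the JSON file.
#' @param layout an [imu_layout()]; rotations are returned in layout order.
#' @return named list (by subject) of lists of 3x3 matrices (by IMU).
#' @export
read_rotations <- function(file, layout) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE, simplifyMatrix = FALSE)
  lapply(raw, function(subj) {
    missing <- setdiff(layout$imu_order, names(subj))
    if (length(missing)) {
      stop(sprintf("rotation file lacks IMUs: %s", paste(missing, collapse = ", ")),
        call. = FALSE
      )
    }
    lapply(layout$imu_order, function(seg) {
      v <- unlist(subj[[seg]])
      if (length(v) != 9L) stop(sprintf("IMU '%s': expected 9 values", seg), call. = FALSE)
      R <- matrix(v, 3L, 3L, byrow = TRUE)
      assert_rotation(R, seg)
      R
    })
  })
}

#' Draw a uniformly random rotation matrix
#'
#' QR-based sampling (Haar measure); useful for tests and synthetic
#' calibration inputs.
#'
#' @param seed optional integer seed.
#' @return a 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
    Q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    Q <- Q %*% diag(d)
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    Q
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
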