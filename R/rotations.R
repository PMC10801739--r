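#' Rotation utilities
#'
#' Quaternions are stored as length-4 numeric vectors `(w, x, y, z)` with
#' unit norm. Body frames are right-handed with +X anterior, +Y left and
#' +Z superior; world gravity acts along -Z. Intervertebral angles are
#' extracted with a fixed Cardan x-y-z sequence (lateral bending about the
#' anterior axis, flexion-extension about the left axis, axial rotation
#' about the superior axis), so a positive flexion angle tips the anterior
#' direction downward.
#'
#' @name rotations
#' @keywords internal
NULL

#' Convert a unit quaternion to a rotation matrix
#' @param q numeric(4), `(w, x, y, z)`; renormalized internally.
#' @return 3x3 rotation matrix.
#' @keywords internal
quat_to_rotmat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#' @param R 3x3 rotation matrix.
#' @return numeric(4) quaternion `(w, x, y, z)`, w >= 0.
#' @keywords internal
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Rotation about a coordinate axis
#' @param axis 1, 2 or 3 (x, y, z).
#' @param angle radians.
#' @keywords internal
axis_rotmat <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  R <- diag(3)
  i <- switch(axis, c(2, 3), c(3, 1), c(1, 2))
  R[i[1], i[1]] <- c_; R[i[2], i[2]] <- c_
  R[i[1], i[2]] <- -s_; R[i[2], i[1]] <- s_
  R
}

#' Cardan x-y-z angles of a rotation matrix
#'
#' Decomposes `R = Rx(a) Ry(b) Rz(c)`: `a` = lateral bending, `b` =
#' flexion-extension, `c` = axial rotation under the package body-frame
#' convention.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric(3) angles in radians `(lateral, flexion, axial)`.
#' @keywords internal
cardan_xyz <- function(R) {
  b <- asin(max(-1, min(1, R[1, 3])))
  a <- atan2(-R[2, 3], R[3, 3])
  c_ <- atan2(-R[1, 2], R[1, 1])
  c(a, b, c_)
}

#' Quaternion product
#' @keywords internal
quat_mult <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
mm2m <- function(x) x / 1000
m2mm <- function(x) x * 1000

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
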