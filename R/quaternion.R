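#' Quaternion algebra in (x, y, z, w) storage order
#'
#' All orientations in stridewise are unit quaternions stored in
#' `(x, y, z, w)` order (vector part first, scalar last), using the Hamilton
#' convention for composition and *active* rotations: `quat_rotate(q, v)`
#' rotates the vector `v` by the rotation `q`. A quaternion series is an
#' `n x 4` numeric matrix with columns `q_x, q_y, q_z, q_w`; a single
#' quaternion is a length-4 numeric vector.
#'
#' @param x,y,z,w quaternion components.
#' @return `quat()` returns a length-4 numeric vector `(x, y, z, w)`.
#' @examples
#' q <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
#' quat_rotate(q, c(1, 0, 0)) # ~ (0, 1, 0)
#' @name quaternions
NULL

#' @rdname quaternions
#' @export
quat <- function(x, y, z, w) c(x, y, z, w)

#' @rdname quaternions
#' @export
quat_identity <- function() c(0, 0, 0, 1)

# coerce a single quaternion or an n x 4 matrix to matrix form
as_quat_matrix <- function(q) {
  if (is.matrix(q)) {
    stopifnot(ncol(q) == 4)
    q
  } else {
    stopifnot(length(q) == 4)
    matrix(q, nrow = 1)
  }
}

#' @rdname quaternions
#' @param q,q1,q2 quaternions: length-4 vectors or n x 4 matrices
#'   (vectorized row-wise; a vector and a matrix are recycled against each
#'   other).
#' @export
quat_norm <- function(q) {
  q <- as_quat_matrix(q)
  sqrt(rowSums(q^2))
}

#' @rdname quaternions
#' @export
quat_normalize <- function(q) {
  single <- !is.matrix(q)
  m <- as_quat_matrix(q)
  n <- quat_norm(m)
  if (any(n == 0)) stop("cannot normalize a zero quaternion")
  m <- m / n
  if (single) drop(m) else m
}

#' @rdname quaternions
#' @export
quat_conjugate <- function(q) {
  single <- !is.matrix(q)
  m <- as_quat_matrix(q)
  m[, 1:3] <- -m[, 1:3]
  if (single) drop(m) else m
}

#' @rdname quaternions
#' @export
quat_multiply <- function(q1, q2) {
  single <- !is.matrix(q1) && !is.matrix(q2)
  a <- as_quat_matrix(q1)
  b <- as_quat_matrix(q2)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), , drop = FALSE]
  stopifnot(nrow(a) == nrow(b))
  x1 <- a[, 1]; y1 <- a[, 2]; z1 <- a[, 3]; w1 <- a[, 4]
  x2 <- b[, 1]; y2 <- b[, 2]; z2 <- b[, 3]; w2 <- b[, 4]
  out <- cbind(
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2,
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2
  )
  colnames(out) <- c("q_x", "q_y", "q_z", "q_w")
  if (single) unname(drop(out)) else out
}

#' Rotate vectors by unit quaternions
#'
#' Applies the active rotation represented by `q` to `v`. Both arguments are
#' vectorized row-wise: `q` may be a single quaternion or an `n x 4` matrix,
#' `v` a single 3-vector or an `n x 3` matrix.
#'
#' @param q unit quaternion(s) in `(x, y, z, w)` order.
#' @param v 3-vector(s) to rotate.
#' @param tol maximum allowed deviation of `|q|` from 1 before an error is
#'   signalled.
#' @return rotated vector(s), same shape as `v` (norm-preserving).
#' @export
quat_rotate <- function(q, v, tol = 1e-6) {
  single <- !is.matrix(v)
  qm <- as_quat_matrix(q)
  vm <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  stopifnot(ncol(vm) == 3)
  if (any(abs(quat_norm(qm) - 1) > tol)) {
    stop("invalid orientation: quaternion is not unit-norm within tolerance")
  }
  n <- max(nrow(qm), nrow(vm))
  if (nrow(qm) == 1 && n > 1) qm <- qm[rep(1, n), , drop = FALSE]
  if (nrow(vm) == 1 && n > 1) vm <- vm[rep(1, n), , drop = FALSE]
  # v' = v + 2 * qv x (qv x v + w v)  (Hamilton, active)
  qv <- qm[, 1:3, drop = FALSE]
  w <- qm[, 4]
  t1 <- cross3(qv, vm) + vm * w
  out <- vm + 2 * cross3(qv, t1)
  if (single) drop(out) else out
}

# row-wise cross product of n x 3 matrices
cross3 <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

#' @rdname quaternions
#' @param axis rotation axis (3-vector, any norm > 0).
#' @param angle rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero")
  axis <- axis / n
  c(axis * sin(angle / 2), cos(angle / 2))
}

#' Convert rotation vectors to quaternions and back
#'
#' A rotation vector is `axis * angle` in radians. `quat_from_rotvec()`
#' accepts an `n x 3` matrix (row-wise) or a single 3-vector;
#' `quat_to_rotvec()` is its inverse on the half-sphere `w >= 0`.
#'
#' @param rv rotation vector(s), radians.
#' @return quaternion(s) / rotation vector(s), matching the input shape.
#' @export
quat_from_rotvec <- function(rv) {
  single <- !is.matrix(rv)
  m <- if (is.matrix(rv)) rv else matrix(rv, nrow = 1)
  angle <- sqrt(rowSums(m^2))
  # sinc-style safe half-angle scaling: sin(a/2)/a -> 1/2 as a -> 0
  k <- ifelse(angle > 1e-12, sin(angle / 2) / pmax(angle, 1e-300), 0.5)
  out <- cbind(m * k, cos(angle / 2))
  colnames(out) <- c("q_x", "q_y", "q_z", "q_w")
  if (single) unname(drop(out)) else out
}

#' @rdname quat_from_rotvec
#' @param q unit quaternion(s).
#' @export
quat_to_rotvec <- function(q) {
  single <- !is.matrix(q)
  m <- as_quat_matrix(q)
  # map to the w >= 0 hemisphere so the angle is in [0, pi]
  flip <- m[, 4] < 0
  m[flip, ] <- -m[flip, , drop = FALSE]
  sv <- sqrt(rowSums(m[, 1:3, drop = FALSE]^2))
  angle <- 2 * atan2(sv, m[, 4])
  k <- ifelse(sv > 1e-12, angle / pmax(sv, 1e-300), 2)
  out <- m[, 1:3, drop = FALSE] * k
  if (single) drop(out) else out
}

#' @rdname quaternions
#' @export
quat_angle <- function(q) {
  m <- as_quat_matrix(q)
  sv <- sqrt(rowSums(m[, 1:3, drop = FALSE]^2))
  ang <- 2 * atan2(sv, abs(m[, 4]))
  if (!is.matrix(q)) drop(ang) else ang
}

#' @rdname quaternions
#' @export
quat_to_matrix <- function(q) {
  stopifnot(length(q) == 4)
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Shortest-arc rotation between two vectors
#'
#' Returns the minimal-angle unit quaternion rotating `from` onto `to`
#' (directions only; norms are ignored). For antiparallel inputs the 180
#' degree rotation about the x-axis is returned as a deterministic
#' tie-break (any axis orthogonal to `from` would do).
#'
#' @param from,to non-zero 3-vectors.
#' @return a unit quaternion in `(x, y, z, w)` order.
#' @export
quat_shortest_arc <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t <- to / sqrt(sum(to^2))
  d <- sum(f * t)
  if (d < -1 + 1e-12) {
    # antiparallel: 180 deg about x (or about z if from ~ x-axis)
    ax <- c(1, 0, 0)
    if (abs(f[1]) > 1 - 1e-9) ax <- c(0, 0, 1)
    ax <- ax - f * sum(ax * f)
    return(quat_from_axis_angle(ax, pi))
  }
  axis <- drop(cross3(matrix(f, 1), matrix(t, 1)))
  w <- sqrt((1 + d) / 2)           # cos(theta/2)
  s <- sqrt(sum(axis^2))
  if (s < 1e-300) return(quat_identity())
  axis <- axis / s * sqrt((1 - d) / 2)  # sin(theta/2) * unit axis
  quat_normalize(c(axis, w))
}
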