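# Rigid-transform and small-twist utilities. Poses are 4x4 row-major-printed
# homogeneous matrices; twists are 6-vectors (v, omega) referenced at a stated
# world point; all lengths mm, angles rad.

#' Skew-symmetric (cross-product) matrix
#'
#' Returns the 3x3 matrix `S` with `S %*% b == cross(a, b)`.
#'
#' @param a numeric length-3 vector.
#' @return 3x3 matrix.
#' @keywords internal
skew <- function(a) {
  matrix(c(0, -a[3], a[2],
           a[3], 0, -a[1],
           -a[2], a[1], 0), 3, 3, byrow = TRUE)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product of two m x 3 matrices.
cross_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

#' Rotation matrix from a rotation vector (Rodrigues)
#' @param w rotation vector (axis * angle, rad).
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_exp <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) {
    S <- skew(w)
    return(diag(3) + S + 0.5 * S %*% S)
  }
  k <- w / th
  S <- skew(k)
  diag(3) + sin(th) * S + (1 - cos(th)) * S %*% S
}

#' Rotation vector from a rotation matrix
#' @param R 3x3 proper rotation matrix.
#' @return length-3 rotation vector (axis * angle, rad).
#' @keywords internal
rot_log <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-9) {
    # first-order: R ~ I + skew(w)
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (th > pi - 1e-6) {
    # near pi: use symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonals
    i <- which.max(ax)
    s <- sign(c(B[1, i], B[2, i], B[3, i]))
    s[s == 0] <- 1
    ax <- ax * s * sign(ax[i])
    return(unit3(ax) * th)
  }
  c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th)) * th
}

rt_identity <- function() diag(4)

rt_make <- function(R, t) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}

rt_rot <- function(T) T[1:3, 1:3]
rt_trans <- function(T) T[1:3, 4]

rt_inverse <- function(T) {
  R <- rt_rot(T)
  rt_make(t(R), -t(R) %*% rt_trans(T))
}

rt_apply <- function(T, p) {
  # p: length-3 vector or m x 3 matrix of points
  if (is.matrix(p)) {
    sweep(p %*% t(rt_rot(T)), 2, rt_trans(T), `+`)
  } else {
    as.numeric(rt_rot(T) %*% p + rt_trans(T))
  }
}

rt_apply_vec <- function(T, v) {
  if (is.matrix(v)) v %*% t(rt_rot(T)) else as.numeric(rt_rot(T) %*% v)
}

#' Apply a twist (v, w) referenced at world point `r` to a pose
#'
#' The material point currently at `r` moves to `r + v`; the body rotates by
#' the rotation vector `w`.
#'
#' @param T 4x4 pose.
#' @param tw length-6 twist `c(v, w)`.
#' @param r length-3 world reference point.
#' @return updated 4x4 pose.
#' @keywords internal
rt_apply_twist <- function(T, tw, r) {
  Rd <- rot_exp(tw[4:6])
  D <- rt_make(Rd, r + tw[1:3] - Rd %*% r)
  D %*% T
}

#' Twist taking pose `T_from` to pose `T_to`, referenced at world point `r`
#'
#' Translation part is the displacement of the material point currently at
#' `r` under `T_from`; rotation part is the rotation vector of the relative
#' rotation.
#' @keywords internal
rt_twist_between <- function(T_from, T_to, r) {
  w <- rot_log(rt_rot(T_to) %*% t(rt_rot(T_from)))
  v <- rt_apply(T_to %*% rt_inverse(T_from), r) - r
  c(v, w)
}

is_rigid_transform <- function(T, tol = 1e-8) {
  is.matrix(T) && all(dim(T) == c(4, 4)) &&
    max(abs(t(rt_rot(T)) %*% rt_rot(T) - diag(3))) < tol &&
    abs(det(rt_rot(T)) - 1) < tol &&
    all(T[4, ] == c(0, 0, 0, 1))
}

# Transport matrix: twist at point b expressed as twist at point a,
# i.e. (v_a, w) = Tm %*% (v_b, w) with v_a = v_b + w x (a - b).
twist_transport <- function(a, b) {
  Tm <- diag(6)
  Tm[1:3, 4:6] <- -skew(a - b)
  Tm
}

# Transport a wrench (F, M) applied at point b to reference point a.
wrench_transport <- function(W, a, b) {
  c(W[1:3], W[4:6] + cross3(b - a, W[1:3]))
}
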