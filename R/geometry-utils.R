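# Internal rigid-body geometry helpers shared by the nucleic-acid and
# structure-comparison code. Angles at the user surface are degrees;
# these helpers take radians unless suffixed _deg.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# Rodrigues rotation about a (non-zero) axis vector.
rot_axis <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# Angle between two vectors in degrees, clamped against rounding.
angle_between_deg <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

# Axis of a rotation matrix (unit vector). For theta -> 0 the axis is
# ill-conditioned; fall back to the dominant eigenvector.
rotation_axis <- function(R) {
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (vnorm(v) > 1e-8) return(unit(v))
  ev <- eigen(R)
  i <- which.min(abs(Re(ev$values) - 1))
  unit(Re(ev$vectors[, i]))
}

# Optimal proper-rotation superposition (Kabsch via SVD).
# P, Q: n x 3 matrices (P mobile, Q reference). Returns rotation R and
# translation t such that P %*% t(R) + t approximates Q, plus the rmsd.
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  n <- nrow(P)
  if (n < 3) stop("superposition needs at least 3 matched points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinearity guard: centered points must span a plane
  if (n >= 3) {
    sv <- svd(Pc)$d
    if (sv[2] < 1e-8 * max(sv[1], 1)) {
      stop("matched points are collinear; superposition is underdetermined")
    }
  }
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

apply_rigid <- function(xyz, R, t) {
  sweep(xyz %*% t(R), 2, t, `+`)
}

# 4x4 homogeneous helpers used by the duplex builder and dimer joiner.
hmat <- function(R, o) {
  H <- diag(4)
  H[1:3, 1:3] <- R
  H[1:3, 4] <- o
  H
}

hrot <- function(H) H[1:3, 1:3]
horg <- function(H) H[1:3, 4]

# Closest proper rotation to an arbitrary 3x3 matrix (used to average
# the two base frames of a pair).
orthonormalize_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}
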