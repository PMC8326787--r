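# Small vector-geometry helpers shared across modules. All coordinates are in
# Angstrom; all matrices are N x 3 with atoms in rows.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle_deg` degrees about the (normalized) `axis`,
#' right-handed. Used throughout the synthetic generator and the invariance
#' tests.
#'
#' @param axis 3-vector, need not be unit length.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix (determinant +1).
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Apply a rigid motion (3x3 rotation R, translation t) to an N x 3 matrix.
transform_coords <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}

# Dihedral angle (degrees, in (-180, 180]) defined by four points, standard
# atan2 formulation. Sign convention: for points 1..4 with the 2->3 bond along
# -z and point 1 rotated by +d degrees (right-handed about +z) relative to
# point 4, the result is +d.
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-12 || vnorm(n2) < 1e-12) {
    stop("undefined dihedral: collinear defining points")
  }
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * unit(b2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Circular mean of angles in degrees, mapped to (-180, 180].
circular_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  m <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  if (m <= -180) m <- m + 360
  m
}

# Axial and perpendicular coordinates of points relative to a pore axis.
# Returns list(axial = t, perp = distance to the axis line).
axis_coords <- function(xyz, axis) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3)
  v <- sweep(xyz, 2, axis$point)
  t_ax <- drop(v %*% axis$direction)
  perp_vec <- v - outer(t_ax, axis$direction)
  list(axial = t_ax, perp = sqrt(rowSums(perp_vec^2)))
}
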