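# Small vector-geometry toolkit shared by the builders, movers and
# observable detectors.  All coordinates are in Angstrom, all angles in
# degrees at the interfaces (radians internally).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle` degrees
#' about the (not necessarily unit) `axis`.
#'
#' @param axis numeric 3-vector, rotation axis.
#' @param angle rotation angle in degrees.
#' @return a 3x3 orthonormal rotation matrix with determinant +1.
#' @keywords internal
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  th <- deg2rad(angle)
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

# Rotate the rows of an n x 3 matrix about the axis through `origin`.
rotate_points <- function(xyz, origin, axis, angle) {
  R <- rotation_about_axis(axis, angle)
  shifted <- sweep(xyz, 2, origin)
  sweep(shifted %*% t(R), 2, origin, FUN = "+")
}

#' Dihedral angle of four points
#'
#' Signed torsion a-b-c-d in degrees, in (-180, 180].
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return angle in degrees.
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

bond_angle <- function(a, b, c) {
  v1 <- unit(a - b)
  v2 <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Positions a new atom `d` given three reference atoms and the internal
#' coordinates bond length d-c, bond angle d-c-b and dihedral d-c-b-a.
#'
#' @param a,b,c numeric 3-vectors; `c` is the parent atom.
#' @param bond bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral torsion a-b-c-d in degrees.
#' @return numeric 3-vector with the new coordinates.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle)
  ph <- deg2rad(dihedral)
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d_local <- c(
    -bond * cos(th),
    bond * sin(th) * cos(ph),
    -bond * sin(th) * sin(ph)
  )
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# All-pairs squared distances between the rows of two n x 3 matrices,
# returned as an nrow(a) x nrow(b) matrix.  Vectorised workhorse for the
# contact and energy code.
cross_dist2 <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  outer(a2, b2, "+") - 2 * tcrossprod(a, b)
}

cross_dist <- function(a, b) sqrt(pmax(cross_dist2(a, b), 0))
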