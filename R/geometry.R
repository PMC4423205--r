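#' Vector and torsion geometry primitives
#'
#' Low-level helpers shared by all structural analyses. Angles are in degrees
#' throughout the package; coordinates are in Angstrom.
#'
#' @name geometry
#' @keywords internal
NULL

DEG <- 180 / pi

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

#' Angle at p2 formed by p1-p2-p3, in degrees
#' @keywords internal
vec_angle <- function(p1, p2, p3) {
  u <- vunit(p1 - p2)
  v <- vunit(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * DEG
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: looking from `p2` to `p3`, the angle is positive when
#' the far bond (`p3`-`p4`) is rotated clockwise relative to the near bond
#' (`p2`-`p1`). Mirror-imaging the four points negates the torsion exactly.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees in `(-180, 180]`.
#' @examples
#' dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)) # cis -> 0
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("undefined torsion: coincident consecutive points")
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined torsion: collinear consecutive points")
  m1 <- vcross(n1, vunit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates (natural extension reference frame)
#'
#' Returns the position of atom D given atoms A, B, C, the bond length C-D, the
#' angle B-C-D and the torsion A-B-C-D.
#'
#' @param a,b,c numeric 3-vectors defining the reference frame.
#' @param bond C-D distance, Angstrom.
#' @param angle B-C-D angle, degrees.
#' @param torsion A-B-C-D torsion, degrees.
#' @return numeric 3-vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle / DEG
  tor <- torsion / DEG
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Rotation matrix for a rotation about an arbitrary axis
#' @param axis numeric 3-vector (need not be unit length).
#' @param theta angle in degrees.
#' @keywords internal
rotation_about <- function(axis, theta) {
  u <- vunit(axis)
  th <- theta / DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

#' Least-squares plane normal of a point set
#' @param xyz n x 3 matrix.
#' @return unit normal of the best-fit plane (sign arbitrary).
#' @keywords internal
plane_normal <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2L, ctr))
  sv$v[, 3L]
}

#' Angle between two directions folded to [0, 90] degrees
#' @keywords internal
axis_angle <- function(u, v) {
  a <- acos(max(-1, min(1, abs(sum(vunit(u) * vunit(v)))))) * DEG
  a
}

#' Deterministic near-uniform points on the unit sphere (golden-angle spiral)
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
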