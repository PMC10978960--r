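# Small 3-vector helpers used throughout the geometric code. All coordinates
# are in Angstrom, all angles in degrees unless noted.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  a / n
}

#' Euclidean distance between two points
#' @param a,b numeric length-3 vectors (Angstrom)
#' @return distance in Angstrom
#' @keywords internal
point_dist <- function(a, b) vnorm(a - b)

# All-pairs distance matrix between the rows of two n x 3 matrices.
dist_matrix <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Dihedral angle defined by four points
#'
#' Signed torsion p1-p2-p3-p4 using the IUPAC convention, in degrees in
#' (-180, 180].
#' @param p1,p2,p3,p4 numeric length-3 vectors
#' @return angle in degrees
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Angle (degrees, [0, 180]) between two vectors.
vec_angle <- function(a, b) {
  ca <- sum(vunit(a) * vunit(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# NeRF atom placement: position a new atom given three reference atoms, a
# bond length to c, the bond angle b-c-new and the torsion a-b-c-new.
# Consistent with dihedral_angle(): dihedral_angle(a, b, c, place_atom(...))
# returns the requested torsion.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  tor <- dihedral * pi / 180
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         -bond * sin(ang) * sin(tor))
  c + bc * d[1] + m * d[2] + n * d[3]
}

# Rotation matrix for a rotation of `deg` degrees about unit axis `axis`
# (Rodrigues). Proper rotation, det +1.
rotation_about_axis <- function(axis, deg) {
  u <- vunit(axis)
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Angle (degrees) of a proper rotation matrix.
rotation_angle_deg <- function(R) {
  tr <- sum(diag(R))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

clamp01 <- function(x) max(0, min(1, x))
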