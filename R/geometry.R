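## Low-level vector geometry shared by the structural modules.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-10) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

#' Dihedral angle of four points
#'
#' Signed torsion angle defined by four points, following the IUPAC
#' convention: the angle is the rotation of the p3-p4 bond relative to the
#' p1-p2 bond when looking along p2-p3, positive clockwise.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (coordinates in angstroms).
#' @return Angle in degrees in the half-open range (-180, 180].
#' @examples
#' compute_dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)) # -90
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  for (p in list(p1, p2, p3, p4)) {
    if (length(p) != 3L || !all(is.finite(p)))
      stop("dihedral points must be finite 3-vectors", call. = FALSE)
  }
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-8 || vnorm(b2) < 1e-8 || vnorm(b3) < 1e-8)
    stop("undefined dihedral: consecutive points coincide", call. = FALSE)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-8 || vnorm(n2) < 1e-8)
    stop("undefined dihedral: collinear points", call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * (b2 / vnorm(b2)))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## Place atom D from reference atoms a-b-c given the c-D bond length,
## the b-c-D angle and the a-b-c-D dihedral (NeRF construction). The
## convention matches compute_dihedral exactly: re-measuring the placed
## dihedral returns `tors`.
place_atom <- function(a, b, c_, dist, ang, tors) {
  ang <- ang * pi / 180
  tors <- tors * pi / 180
  bc <- unitv(c_ - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-dist * cos(ang), dist * sin(ang) * cos(tors), dist * sin(ang) * sin(tors))
  c_ + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

## Rotation matrix for `angle` degrees about unit axis (Rodrigues form).
rotation_matrix <- function(axis, angle) {
  u <- unitv(axis)
  th <- angle * pi / 180
  ct <- cos(th)
  st <- sin(th)
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) * ct + st * K + (1 - ct) * (u %o% u)
}

## Rotate the rows of xyz (n x 3) about the line through `origin` along `axis`.
rotate_points <- function(xyz, origin, axis, angle) {
  R <- rotation_matrix(axis, angle)
  shifted <- sweep(xyz, 2L, origin)
  sweep(shifted %*% t(R), 2L, origin, `+`)
}

## All cross distances between two coordinate matrices (na x 3, nb x 3).
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}
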