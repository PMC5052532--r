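# Low-level vector geometry shared by detectors, rotamer calling and the
# fixture generators.  All coordinates are Cartesian Angstrom.

.vnorm <- function(v) sqrt(sum(v * v))

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at vertex b formed by points a-b-c
#'
#' @param a,b,c Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in \[0, 180\].
#' @export
vec_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Signed dihedral (torsion) angle of four points
#'
#' IUPAC sign convention for torsions: looking down the p2->p3 axis, the
#' angle from the p1-p2 bond to the p3-p4 bond, positive clockwise, in
#' (-180, 180].  Invariant under rigid rotation and translation; the sign
#' flips under mirror reflection.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Torsion angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.vnorm(n1) < 1e-8 * .vnorm(b1) * .vnorm(b2) ||
      .vnorm(n2) < 1e-8 * .vnorm(b2) * .vnorm(b3))
    stop("undefined torsion: three consecutive points are collinear")
  b2u <- b2 / .vnorm(b2)
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, n2) * b2u)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Least-squares plane through a point cloud; returns centroid, unit
# normal and the RMS out-of-plane deviation.
.fit_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  normal <- sv$v[, 3]
  dev <- as.vector(sweep(xyz, 2, ctr) %*% normal)
  list(centroid = ctr, normal = normal, rms = sqrt(mean(dev^2)))
}

# All pairwise distances between two coordinate matrices (n x 3, m x 3).
.pair_dists <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Deterministic uniform random rotation matrix from a seed-driven RNG
# stream (caller controls set.seed).
.random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply rotation R then translation t to an n x 3 matrix.
.apply_rigid <- function(xyz, rot, trans = c(0, 0, 0)) {
  sweep(matrix(as.numeric(xyz), ncol = 3) %*% t(rot), 2, trans, "+")
}
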