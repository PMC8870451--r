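# 3-D geometry: dihedrals, internal-coordinate placement, Kabsch superposition.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.normalize <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) .stopf("cannot normalize a near-zero vector")
  v / n
}

#' Dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: looking down the p2-p3 bond, the angle is positive
#' when p4 is rotated clockwise from p1. Result is wrapped to (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees, or `NA` if any three consecutive points are
#'   colinear (torsion undefined).
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  if (sum(n1 * n1) < 1e-16 || sum(n2 * n2) < 1e-16) return(NA_real_)
  b2u <- b2 / sqrt(sum(b2 * b2))
  x <- sum(n1 * n2)
  y <- sum(.cross3(n1, b2u) * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place atom D from A-B-C with bond length r (C-D), angle theta (B-C-D) and
# torsion chi (A-B-C-D), both in degrees. Inverse of dihedral_angle by
# construction.
.place_dihedral <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  b1 <- .normalize(C - B)
  b0 <- .normalize(B - A)
  n <- .normalize(.cross3(b0, b1))
  m <- .cross3(n, b1)
  d <- r * (-cos(th) * b1 + sin(th) * (cos(ch) * m - sin(ch) * n))
  C + d
}

# Optimal rotation (Kabsch) superposing `mobile` onto `ref` (both n x 3,
# n >= 3). Returns list(R, t) with aligned = mobile %*% R + t (row-vectors).
.kabsch <- function(mobile, ref) {
  if (nrow(mobile) < 3L) .stopf("superposition needs at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2L, cm); Q <- sweep(ref, 2L, cr)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = cr - drop(cm %*% R))
}

.apply_rigid <- function(coords, R, t) sweep(coords %*% R, 2L, -t, `-`)

# well separated unit directions: octahedron axes then cube diagonals
.direction_table <- local({
  ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  dg <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1))) / sqrt(3)
  colnames(dg) <- NULL
  rbind(ax, dg)
})
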