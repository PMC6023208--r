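# Low-level 3D geometry helpers shared by the structure and rotamer code.
# All coordinates are numeric length-3 vectors in Angstroms; angles in degrees.

vec_norm <- function(v) sqrt(sum(v * v))

#' Angle p0-p1-p2 in degrees
#' @noRd
vec_angle <- function(p0, p1, p2) {
  v1 <- p0 - p1
  v2 <- p2 - p1
  cosang <- sum(v1 * v2) / (vec_norm(v1) * vec_norm(v2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Signed dihedral p0-p1-p2-p3 in degrees, IUPAC convention, range (-180, 180]
#' @noRd
vec_dihedral <- function(p0, p1, p2, p3) {
  b0 <- p0 - p1
  b1 <- p2 - p1
  b2 <- p3 - p2
  b1 <- b1 / vec_norm(b1)
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  y <- sum(cross3(b1, v) * w)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom X from frame atoms (a, b, c) so that |X - c| = len,
#' angle(X, c, b) = ang and dihedral(a, b, c, X) = tau (NeRF construction).
#' @noRd
place_atom <- function(a, b, c, len, ang, tau) {
  ang <- ang * pi / 180
  tau <- tau * pi / 180
  d <- c(-len * cos(ang),
         len * sin(ang) * cos(tau),
         len * sin(ang) * sin(tau))
  bc <- c - b
  bc <- bc / vec_norm(bc)
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / vec_norm(n)
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d + c)
}

#' Minimum Euclidean distance between row sets of two coordinate matrices
#' @noRd
min_cross_dist <- function(A, B) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}
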