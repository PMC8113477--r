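## Core geometric operations: signed dihedrals, Kabsch superposition, RMSD.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: the angle is 0 for a cis (eclipsed) arrangement and
#' +/-180 for anti, positive when, looking from atom 2 towards atom 3, the
#' far bond is rotated clockwise relative to the near bond.
#'
#' @param p1,p2,p3,p4 length-3 coordinates.
#' @return angle in degrees in (-180, 180], or NA if the three bond vectors
#'   degenerate (collinear middle atoms).
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 == 0 || sum(n1^2) < 1e-14 || sum(n2^2) < 1e-14) return(NA_real_)
  atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2)) * 180 / pi
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation (determinant +1 enforced, so reflections are never
#' introduced) and translation mapping `mobile` onto `target`.
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows (n >= 3).
#' @return list with `R` (3 x 3 rotation applied on the right:
#'   `mobile %*% R`), the centroids, and `xyz`, the superposed mobile
#'   coordinates.
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (nrow(mobile) < 3) stop("superposition needs at least 3 atoms", call. = FALSE)
  stopifnot(all(dim(mobile) == dim(target)))
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  xyz <- sweep(P %*% R, 2, ct, "+")
  list(R = R, mobile_centroid = cm, target_centroid = ct, xyz = xyz)
}

#' Root-mean-square deviation between matched coordinate sets
#'
#' @param a,b n x 3 matrices with matched rows.
#' @param superpose optimally superpose `a` onto `b` first (default FALSE).
#' @return RMSD in the coordinate units.
#' @export
rmsd <- function(a, b, superpose = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (superpose) a <- kabsch_superpose(a, b)$xyz
  sqrt(mean(rowSums((a - b)^2)))
}
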