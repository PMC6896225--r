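#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between a
#' mobile point set and a reference, in closed form via the SVD of the
#' cross-covariance matrix. Reflections are excluded: the returned rotation
#' always has determinant +1.
#'
#' @param mobile,reference numeric matrices (n x 3), nm, equal row counts
#'   (n >= 3, not all collinear).
#' @return list with `transform` (a [RigidTransform-class] mapping mobile
#'   onto reference as `x R' + t`) and `rmsd`, the post-fit RMSD in
#'   Angstrom.
#' @export
superposeKabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 ||
      ncol(reference) != 3)
    rwStop("rw_size_error", "mobile and reference must be n x 3 with equal n")
  if (nrow(mobile) < 3)
    rwStop("rw_geometry_error", "at least 3 points required")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  P <- sweep(mobile, 2, mc); Q <- sweep(reference, 2, rc)
  # collinear (or coincident) point sets leave the rotation underdetermined
  sv <- svd(P)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12))
    rwStop("rw_geometry_error",
           "degenerate (collinear) point set: rotation underdetermined")
  H <- crossprod(P, Q)          # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(rc - R %*% mc)
  fitted <- tcrossprod(mobile, R) + matrix(tr, nrow(mobile), 3, byrow = TRUE)
  list(
    transform = new("RigidTransform", rotation = R, translation = tr),
    rmsd = 10 * sqrt(mean(rowSums((fitted - reference)^2)))
  )
}

#' Apply a RigidTransform to coordinates
#'
#' @param transform a [RigidTransform-class].
#' @param x numeric matrix (n x 3), nm.
#' @return transformed coordinates.
#' @export
applyTransform <- function(transform, x) {
  tcrossprod(as.matrix(x), transform@rotation) +
    matrix(transform@translation, nrow(x), 3, byrow = TRUE)
}

#' Root-mean-square deviation between two configurations
#'
#' Lab-frame by default, which is the convention for monitoring convergence
#' under a lab-frame harmonic bias; with `fit = TRUE` the mobile set is
#' first superposed onto the reference (Kabsch), removing rigid-body
#' motion.
#'
#' @param a,b numeric matrices (n x 3), nm.
#' @param fit logical; superpose `a` onto `b` first.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, fit = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3)
    rwStop("rw_size_error", "coordinate sets must be n x 3 with equal n")
  if (fit) return(superposeKabsch(a, b)$rmsd)
  10 * sqrt(mean(rowSums((a - b)^2)))
}

#' Rotate coordinates about an arbitrary axis
#'
#' Rodrigues rotation of a point set about the axis through `axisPoint`
#' with direction `axisDir`, by `angleDeg` degrees (right-handed).
#'
#' @param x numeric matrix (n x 3).
#' @param axisPoint point on the axis, numeric(3).
#' @param axisDir axis direction (any nonzero vector; normalised
#'   internally).
#' @param angleDeg rotation angle, degrees.
#' @return rotated coordinates.
#' @export
rotateAboutAxis <- function(x, axisPoint, axisDir, angleDeg) {
  nrm <- sqrt(sum(axisDir^2))
  if (!is.finite(nrm) || nrm == 0)
    rwStop("rw_geometry_error", "axis direction must be nonzero")
  R <- rotationMatrixAxis(axisDir / nrm, angleDeg)
  x <- as.matrix(x)
  sweep(tcrossprod(sweep(x, 2, axisPoint), R), 2, -axisPoint)
}

#' Rotation matrix about a unit axis (Rodrigues form)
#' @noRd
rotationMatrixAxis <- function(u, angleDeg) {
  th <- angleDeg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c1 + s1 * K + (1 - c1) * tcrossprod(u)
}
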