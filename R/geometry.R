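#' Rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` by singular value
#' decomposition of the covariance matrix, with the reflection guard that
#' enforces a proper rotation (det = +1). Weights are uniform.
#'
#' @param mobile n x 3 coordinate matrix (Angstrom).
#' @param reference n x 3 coordinate matrix, same point order.
#' @return a `rigid_transform`: list with `rotation` (3 x 3), `translation`
#'   (length 3) and `rmsd` (Angstrom, after fitting). The transform maps a
#'   row vector x to `x %*% t(rotation) + translation`.
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop("mobile and reference must be n x 3 matrices of equal size")
  }
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2L, cm); B <- sweep(reference, 2L, cr)
  # collinear (or coincident) point sets leave the rotation about the
  # common axis undetermined
  if (svd(A, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, svd(A, nu = 0, nv = 0)$d[1]) ||
      svd(B, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, svd(B, nu = 0, nv = 0)$d[1])) {
    stop("degenerate (collinear) point set: superposition is ill-defined")
  }
  H <- crossprod(A, B)              # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)       # maps mobile-centred coords onto reference
  t_vec <- as.numeric(cr - R %*% cm)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rmsd after fit =", format(x$rmsd, digits = 4), "A\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#' @param tr a `rigid_transform` from [kabsch_fit()].
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(tr, xyz) {
  stopifnot(inherits(tr, "rigid_transform"))
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(tr$rotation), 2L, tr$translation, "+")
}

#' RMSD without refitting
#'
#' Root-mean-square deviation between two matched coordinate sets in their
#' current frame — used for ligand RMSD after the receptor has been
#' aligned, so ligand translation relative to the pocket is retained.
#'
#' @param a,b n x 3 coordinate matrices, matched point order.
#' @return RMSD in Angstrom.
#' @export
rmsd_no_fit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Minimum pairwise distance between two coordinate sets
#' @param a,b coordinate matrices (rows are points).
#' @return minimum Euclidean distance in Angstrom.
#' @export
min_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty coordinate set")
  d2 <- cross_dist2(a, b)
  sqrt(max(0, min(d2)))
}

# squared Euclidean cross-distance matrix, |a| x |b|
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
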