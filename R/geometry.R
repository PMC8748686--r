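# Rigid-body superposition and RMSD primitives.
#
# Coordinate sets are plain N x 3 numeric matrices; optional rownames act as
# atom labels and, when present on both arguments, must match in order.

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation that minimise the RMSD of `mov`
#' onto `ref`, via SVD of the covariance matrix with the usual determinant
#' correction so that no reflection is ever returned.
#'
#' @param ref,mov N x 3 coordinate matrices with matching point order, N >= 3.
#' @return list with `R` (3x3 rotation, det +1), `t` (length-3 translation,
#'   so that `mov %*% t(R) + t` superposes onto `ref`) and `rmsd`, the
#'   post-superposition RMSD in Angstrom.
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' fit <- kabschSuperpose(p, p)
#' fit$rmsd  # 0
#' @export
kabschSuperpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov))
    stop("point counts differ: ", nrow(ref), " vs ", nrow(mov))
  if (nrow(ref) < 3L)
    stop("at least 3 points are required for superposition")
  checkLabels(ref, mov)
  cref <- colMeans(ref); cmov <- colMeans(mov)
  A <- sweep(ref, 2, cref); B <- sweep(mov, 2, cmov)
  H <- crossprod(B, A)                      # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate point set: covariance rank < 2")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- as.numeric(cref - R %*% cmov)
  moved <- mov %*% t(R) + matrix(t, nrow(mov), 3, byrow = TRUE)
  list(R = R, t = t, rmsd = coordRmsd(ref, moved, .checkLabels = FALSE))
}

#' Apply a rigid transform to a coordinate set
#'
#' @param transform list with rotation `R` and translation `t`, as returned
#'   by [kabschSuperpose()].
#' @param coords N x 3 matrix.
#' @return transformed N x 3 matrix; rownames preserved.
#' @export
applyTransform <- function(transform, coords) {
  coords <- as.matrix(coords)
  out <- coords %*% t(transform$R) +
    matrix(transform$t, nrow(coords), 3, byrow = TRUE)
  rownames(out) <- rownames(coords)
  out
}

#' Invert a rigid transform
#' @inheritParams applyTransform
#' @return the inverse transform list.
#' @export
invertTransform <- function(transform) {
  Rinv <- t(transform$R)
  list(R = Rinv, t = as.numeric(-Rinv %*% transform$t))
}

#' Unfitted root-mean-square deviation between paired coordinates
#'
#' No superposition is performed: the two sets must already be in the same
#' frame and paired row by row.
#'
#' @param a,b N x 3 matrices with matching row order (and matching rownames
#'   when both carry them).
#' @return RMSD in Angstrom.
#' @export
coordRmsd <- function(a, b, .checkLabels = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("point counts differ: ", nrow(a), " vs ", nrow(b))
  if (nrow(a) == 0L) stop("empty coordinate sets")
  if (.checkLabels) checkLabels(a, b)
  sqrt(mean(rowSums((a - b)^2)))
}

checkLabels <- function(a, b) {
  la <- rownames(a); lb <- rownames(b)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("coordinate labels do not match")
  invisible(NULL)
}

#' Minimum cross-set distance and within-cutoff tests
#'
#' Workhorse for contact rules: for two coordinate matrices returns the
#' minimum pairwise Euclidean distance.
#'
#' @param a,b coordinate matrices (N x 3, M x 3).
#' @return smallest distance between any row of `a` and any row of `b`.
#' @export
minCrossDist <- function(a, b) {
  sqrt(max(0, min(crossDist2(a, b))))
}

# squared distance matrix between rows of a and rows of b
crossDist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty coordinate set")
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' @describeIn minCrossDist TRUE when any cross-set pair is within `cutoff`.
#' @param cutoff distance cutoff in Angstrom.
#' @export
anyWithin <- function(a, b, cutoff) {
  minCrossDist(a, b) <= cutoff
}

atomCoords <- function(atoms) {
  m <- cbind(atoms$x, atoms$y, atoms$z)
  colnames(m) <- c("x", "y", "z")
  m
}
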