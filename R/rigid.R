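# Rigid-transform estimation and manipulation.
#
# The estimator is the weighted Kabsch solution: weighted centroiding, SVD of
# the weighted cross-covariance, and a determinant sign correction so a
# reflection is never returned. Weights shape the estimate itself (not only
# the objective), which is what lets the median weighting damp wrong matches.

#' Weighted least-squares rigid transform between paired points
#'
#' Finds the rotation R and translation t minimizing
#' \eqn{\sum_i w_i \|R f_i + t - r_i\|^2} over proper rigid transforms
#' (weighted Kabsch: weighted centroids, SVD of the weighted cross-covariance,
#' reflection corrected by a sign flip on the smallest singular direction).
#'
#' @param floatingPoints,referencePoints numeric n x 3 matrices of paired
#'   points (row i of one corresponds to row i of the other), mm.
#' @param weights positive weights, one per pair (default uniform). The
#'   estimate is invariant to uniform rescaling of the weights.
#' @return A [RigidTransform-class].
#' @examples
#' ref <- matrix(rnorm(30), 10, 3)
#' tf <- rigidTransform(diag(3), c(5, 0, 0))
#' flo <- coords(applyTransform(invertTransform(tf), PointCloud(ref)))
#' estimateRigidTransform(flo, ref)
#' @export
estimateRigidTransform <- function(floatingPoints, referencePoints,
                                   weights = NULL) {
  f <- as.matrix(floatingPoints)
  r <- as.matrix(referencePoints)
  n <- nrow(f)
  if (n < 3 || nrow(r) != n)
    stop("need at least 3 paired points with equal counts")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0) || !all(is.finite(weights)))
    stop("weights must be positive and finite, one per pair")
  w <- weights / sum(weights)
  cf <- colSums(f * w)
  cr <- colSums(r * w)
  fc <- sweep(f, 2, cf)
  rc <- sweep(r, 2, cr)
  H <- crossprod(fc * w, rc)  # sum_i w_i (f_i - cf)(r_i - cr)^T
  sv <- svd(H)
  if (sv$d[2] <= max(sv$d[1], .Machine$double.eps) * 1e-8)
    stop("degenerate geometry: paired points are (near-)collinear, rotation is not identifiable")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigidTransform(R, cr - as.vector(R %*% cf))
}

#' Apply a rigid transform to a point cloud
#'
#' Maps every point (and every marker) p to \code{R p + t}. Pairwise
#' distances are preserved.
#'
#' @param transform a [RigidTransform-class]
#' @param x a [PointCloud-class] or an n x 3 coordinate matrix
#' @return object of the same kind as \code{x}, transformed.
#' @export
applyTransform <- function(transform, x) {
  R <- rotation(transform)
  tv <- translation(transform)
  if (is(x, "PointCloud")) {
    co <- coords(x) %*% t(R)
    co <- sweep(co, 2, tv, "+")
    colnames(co) <- c("x", "y", "z")
    mk <- markers(x)
    if (nrow(mk) > 0) {
      m <- as.matrix(mk[, c("x", "y", "z")]) %*% t(R)
      m <- sweep(m, 2, tv, "+")
      mk$x <- m[, 1]; mk$y <- m[, 2]; mk$z <- m[, 3]
    }
    PointCloud(co, mk, source = x@source)
  } else {
    sweep(as.matrix(x) %*% t(R), 2, tv, "+")
  }
}

#' Compose two rigid transforms
#'
#' \code{composeTransforms(t2, t1)} is the transform applying \code{t1}
#' first, then \code{t2}: its matrix form is the homogeneous product.
#'
#' @param t2,t1 [RigidTransform-class] objects
#' @return the composed [RigidTransform-class].
#' @export
composeTransforms <- function(t2, t1) {
  R2 <- rotation(t2); R1 <- rotation(t1)
  rigidTransform(R2 %*% R1,
                 as.vector(R2 %*% translation(t1)) + translation(t2))
}

#' Invert a rigid transform
#' @param transform a [RigidTransform-class]
#' @return the inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  R <- rotation(transform)
  rigidTransform(t(R), -as.vector(t(R) %*% translation(transform)))
}

#' Six-parameter view of a rigid transform
#'
#' Parameters are extrinsic fixed-axis Euler angles applied X then Y then Z
#' (radians, each in (-pi, pi]) followed by the translation (mm):
#' \code{c(rx, ry, rz, tx, ty, tz)}. The rotation matrix is
#' \code{Rz(rz) Ry(ry) Rx(rx)}. \code{toParameters} and
#' \code{fromParameters} are mutually inverse away from gimbal lock
#' (|ry| near pi/2), where \code{toParameters} raises an error.
#'
#' @param transform a [RigidTransform-class]
#' @return numeric length-6 named vector.
#' @export
toParameters <- function(transform) {
  R <- rotation(transform)
  sy <- -R[3, 1]
  sy <- min(1, max(-1, sy))
  ry <- asin(sy)
  if (abs(abs(ry) - pi / 2) < 1e-6)
    stop("gimbal lock: pitch within 1e-6 of +/- pi/2, Euler angles are not unique")
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  stats::setNames(c(rx, ry, rz, translation(transform)),
                  c("rx", "ry", "rz", "tx", "ty", "tz"))
}

#' @rdname toParameters
#' @param params numeric length-6 vector \code{c(rx, ry, rz, tx, ty, tz)}
#'   (radians and mm).
#' @export
fromParameters <- function(params) {
  params <- as.numeric(params)
  if (length(params) != 6 || !all(is.finite(params)))
    stop("params must be six finite numbers")
  a <- params[1]; b <- params[2]; c_ <- params[3]
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c_), sin(c_), 0, -sin(c_), cos(c_), 0, 0, 0, 1), 3, 3)
  rigidTransform(Rz %*% Ry %*% Rx, params[4:6])
}

#' Componentwise difference between two transforms
#'
#' The six-vector gamma of absolute differences between the parameter views
#' of two transforms: per-axis rotation differences (radians, wrapped to
#' (-pi, pi] before taking absolute values) and per-axis translation
#' differences (mm). This is the perturbation range of the I-ICP escape
#' mechanism.
#'
#' @param tInit,tTemp [RigidTransform-class] objects
#' @return non-negative numeric length-6 vector.
#' @export
transformDifference <- function(tInit, tTemp) {
  p1 <- toParameters(tInit)
  p2 <- toParameters(tTemp)
  g <- c(abs(wrapAngle(p1[1:3] - p2[1:3])), abs(p1[4:6] - p2[4:6]))
  unname(g)
}
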