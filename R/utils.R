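# Internal helpers.

# Wrap angles to (-pi, pi].
wrapAngle <- function(x) {
  y <- ((x + pi) %% (2 * pi)) - pi
  y[y == -pi] <- pi
  y
}

bboxDiagonal <- function(cloud) {
  co <- coords(cloud)
  rng <- apply(co, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched. All stochastic draws inside a registration flow from here.
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Geodesic angle (degrees) between the rotations of two transforms.
#' Rotation angle between two rigid transforms
#'
#' The geodesic distance on SO(3) between the two rotation parts, in degrees;
#' used to report rotation recovery error against a known ground truth.
#'
#' @param t1,t2 [RigidTransform-class] objects (\code{t2} defaults to the
#'   identity, giving the rotation magnitude of \code{t1}).
#' @return angle in degrees, in \code{[0, 180]}.
#' @export
rotationAngle <- function(t1, t2 = rigidTransform()) {
  R <- rotation(t1) %*% t(rotation(t2))
  c <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c))) * 180 / pi
}

#' Rotation about an arbitrary axis expressed as extrinsic XYZ Euler angles
#'
#' Convenience for protocols stated as a single composite rotation (e.g. 30
#' degrees about the (1,1,1) diagonal): builds the axis-angle rotation and
#' returns the equivalent Euler angles in degrees, suitable for
#' [makeRegistrationCase()].
#'
#' @param angleDeg rotation angle in degrees.
#' @param axis numeric length-3 axis (normalized internally).
#' @return numeric length-3 Euler angles in degrees (extrinsic X, Y, Z).
#' @examples
#' axisAngleToEulerDeg(30, c(1, 1, 1))
#' @export
axisAngleToEulerDeg <- function(angleDeg, axis = c(1, 1, 1)) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  p <- toParameters(rigidTransform(R))
  p[1:3] * 180 / pi
}
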