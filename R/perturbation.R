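# The escape mechanism: golden-section line minimization, the parabolic
# perturbation sampler, and the expanding-range schedule for alpha.

#' Golden-section minimization on an interval
#'
#' Standard golden-section interval reduction with ratio
#' \eqn{\varphi = (\sqrt{5}-1)/2 \approx 0.618}: at each step the function is
#' compared at the two interior golden points and the sub-interval that
#' cannot contain the bracketed minimum of a unimodal function is discarded.
#' Returns the midpoint of the final interval once its width drops below
#' \code{tol} or \code{maxEvals} evaluations have been spent.
#'
#' @param f scalar function of one variable.
#' @param m,n interval bounds, \code{m < n}.
#' @param tol positive width tolerance on the final interval.
#' @param maxEvals cap on function evaluations.
#' @return list with \code{minimum} (abscissa), \code{objective}
#'   (\code{f(minimum)}) and \code{evaluations}.
#' @examples
#' goldenSectionMinimize(function(x) (x - 1)^2, 0, 5, tol = 1e-6)$minimum
#' @export
goldenSectionMinimize <- function(f, m, n, tol = 1e-6, maxEvals = 100L) {
  if (!is.numeric(m) || !is.numeric(n) || m >= n)
    stop("need interval bounds m < n")
  if (tol <= 0) stop("tol must be positive")
  phi <- (sqrt(5) - 1) / 2
  a <- m; b <- n
  fcheck <- function(x) {
    v <- f(x)
    if (!is.finite(v)) stop(sprintf("non-finite objective value at x = %g", x))
    v
  }
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- fcheck(x1); f2 <- fcheck(x2)
  evals <- 2L
  while ((b - a) >= tol && evals < maxEvals) {
    if (f1 > f2) {  # minimum cannot lie in [a, x1)
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- fcheck(x2)
    } else {        # minimum cannot lie in (x2, b]
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- fcheck(x1)
    }
    evals <- evals + 1L
  }
  xmin <- (a + b) / 2
  list(minimum = xmin, objective = fcheck(xmin), evaluations = evals + 1L)
}

#' Draw from the parabolic perturbation density
#'
#' Samples from \eqn{p(y) = 3y^2 / (2 (\alpha\gamma)^3)} on
#' \eqn{(-\alpha\gamma, \alpha\gamma)}, zero outside: probability mass is
#' concentrated near the interval ends, so large jumps — the ones that can
#' clear the basin of a local minimum — are favoured over small ones.
#' Implemented by inversion, see [parabolicQuantile()].
#'
#' @param alphaGamma positive half-width of the support.
#' @param n number of draws.
#' @return numeric vector of n draws in \code{(-alphaGamma, alphaGamma)}.
#' @export
sampleParabolic <- function(alphaGamma, n = 1L) {
  parabolicQuantile(stats::runif(n), alphaGamma)
}

#' @rdname sampleParabolic
#' @param u probabilities in \code{[0, 1]}; the quantile function is
#'   \eqn{y(u) = \mathrm{sign}(2u-1)\,\alpha\gamma\,|2u-1|^{1/3}}.
#' @export
parabolicQuantile <- function(u, alphaGamma) {
  if (!is.numeric(alphaGamma) || length(alphaGamma) != 1 || alphaGamma <= 0)
    stop("alphaGamma must be a positive scalar")
  s <- 2 * u - 1
  sign(s) * alphaGamma * abs(s)^(1 / 3)
}

#' Propose a perturbed transform around the current best
#'
#' Adds an independent parabolic draw with half-width \eqn{\alpha\gamma_k} to
#' each of the six parameters of \code{tBest} (extrinsic XYZ Euler angles and
#' translation) and maps back to a rigid transform. Zero components of gamma
#' are floored by \code{jitter} so the mechanism never degenerates to a null
#' perturbation. Proposals whose pitch falls within gimbal lock are rejected
#' and re-sampled (at most 100 attempts).
#'
#' @param tBest the current best [RigidTransform-class].
#' @param gamma non-negative length-6 vector from [transformDifference()].
#' @param alpha current range-expansion factor (>= 1).
#' @param jitter length-6 floor applied componentwise to gamma.
#' @return a valid [RigidTransform-class] proposal.
#' @export
proposePerturbedTransform <- function(tBest, gamma, alpha = 1,
                                      jitter = rep(1e-3, 6)) {
  if (length(gamma) != 6 || any(gamma < 0))
    stop("gamma must be a non-negative length-6 vector")
  p0 <- toParameters(tBest)
  half <- alpha * pmax(gamma, jitter)
  for (attempt in seq_len(100L)) {
    offs <- vapply(half, function(h) parabolicQuantile(stats::runif(1), h),
                   numeric(1))
    p <- unname(p0) + offs
    p[1:3] <- wrapAngle(p[1:3])
    if (abs(abs(p[2]) - pi / 2) >= 1e-6)
      return(fromParameters(p))
  }
  stop("100 consecutive gimbal-locked proposals: pathological gamma")
}

# Perturbation-range schedule: reset on improvement, geometric growth on
# failure, capped. State is a plain list(alpha, roundsWithoutImprovement).
newPerturbationState <- function(config) {
  list(alpha = config@alphaStart, roundsWithoutImprovement = 0L)
}

#' Update the perturbation range factor alpha
#'
#' On improvement alpha resets to its starting value and the failure counter
#' clears; otherwise alpha grows geometrically (\code{alphaFactor}) up to
#' \code{alphaMax}, widening the escape range until the stop condition ends
#' the search.
#'
#' @param state list with elements \code{alpha} and
#'   \code{roundsWithoutImprovement}.
#' @param improved logical: did the last round improve the best objective?
#' @param config a [RegistrationConfig-class] providing the schedule
#'   constants.
#' @return the updated state list.
#' @export
updateAlpha <- function(state, improved, config = registrationConfig()) {
  if (improved) {
    state$alpha <- config@alphaStart
    state$roundsWithoutImprovement <- 0L
  } else {
    state$alpha <- min(state$alpha * config@alphaFactor, config@alphaMax)
    state$roundsWithoutImprovement <- state$roundsWithoutImprovement + 1L
  }
  state
}
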