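# The registration drivers: inner ICP loop, the I-ICP outer loop
# (ICP alignment -> evaluation -> stop condition -> perturbation), and the
# classic-ICP baseline as the degenerate configuration.

#' Build a registration configuration
#'
#' All arguments have working defaults; see [RegistrationConfig-class] for
#' the meaning of each. \code{rmsThreshold = NA} resolves at run time to
#' 1e-4 times the reference bounding-box diagonal.
#'
#' @param rmsThreshold stop threshold on the objective (mm), or NA for auto.
#' @param maxOuterRounds maximum outer recursions (default 100).
#' @param maxInnerIterations inner ICP iteration cap (default 100).
#' @param innerDeltaTol inner convergence tolerance on the objective, mm
#'   (default 1e-6).
#' @param weighting "median" or "uniform".
#' @param medianRule "index" or "midpoint".
#' @param objective "weighted_mean" or "rms".
#' @param weightedEstimation logical, weights shape the transform estimate.
#' @param perturbation logical, enable the stochastic escape stage.
#' @param goldenSection logical, refine restart points by golden-section.
#' @param alphaStart,alphaFactor,alphaMax perturbation-range schedule.
#' @param jitterRotDeg,jitterTransFrac zero-gamma floors (degrees; fraction
#'   of the reference bounding-box diagonal).
#' @param gsTolFrac,gsMaxEvals,gsLower,gsUpper golden-section controls.
#' @param seed integer master seed.
#' @param coarseInit "none" or "centroid_pca".
#' @return A [RegistrationConfig-class].
#' @export
registrationConfig <- function(rmsThreshold = NA_real_,
                               maxOuterRounds = 100L,
                               maxInnerIterations = 100L,
                               innerDeltaTol = 1e-6,
                               weighting = c("median", "uniform"),
                               medianRule = c("index", "midpoint"),
                               objective = c("weighted_mean", "rms"),
                               weightedEstimation = TRUE,
                               perturbation = TRUE,
                               goldenSection = TRUE,
                               alphaStart = 1, alphaFactor = 1.5,
                               alphaMax = 20,
                               jitterRotDeg = 1, jitterTransFrac = 0.01,
                               gsTolFrac = 1e-3, gsMaxEvals = 50L,
                               gsLower = 0.5, gsUpper = 1.25,
                               seed = 1L,
                               coarseInit = c("none", "centroid_pca")) {
  new("RegistrationConfig",
      rmsThreshold = as.numeric(rmsThreshold),
      maxOuterRounds = as.integer(maxOuterRounds),
      maxInnerIterations = as.integer(maxInnerIterations),
      innerDeltaTol = innerDeltaTol,
      weighting = match.arg(weighting), medianRule = match.arg(medianRule),
      objective = match.arg(objective),
      weightedEstimation = isTRUE(weightedEstimation),
      perturbation = isTRUE(perturbation),
      goldenSection = isTRUE(goldenSection),
      alphaStart = alphaStart, alphaFactor = alphaFactor, alphaMax = alphaMax,
      jitterRotDeg = jitterRotDeg, jitterTransFrac = jitterTransFrac,
      gsTolFrac = gsTolFrac, gsMaxEvals = as.integer(gsMaxEvals),
      gsLower = gsLower, gsUpper = gsUpper, seed = as.integer(seed),
      coarseInit = match.arg(coarseInit))
}

.checkRegistrationInputs <- function(floating, reference) {
  fp <- coords(floating)
  if (nrow(fp) < 3) stop("registration needs at least 3 floating points")
  sv <- svd(sweep(fp, 2, colMeans(fp)))$d
  if (sv[2] <= max(sv[1], .Machine$double.eps) * 1e-8)
    stop("degenerate geometry: floating points are (near-)collinear")
  invisible(TRUE)
}

#' One inner ICP run from a starting transform
#'
#' Repeats move -> nearest correspondences -> median -> weights -> objective
#' -> weighted least-squares estimate -> compose, until the objective changes
#' by less than \code{innerDeltaTol} or \code{maxInnerIterations} is reached.
#' With uniform weighting (and the perturbation stage off in the caller) this
#' is exactly classic point-to-point ICP.
#'
#' @param floating,reference [PointCloud-class] objects.
#' @param tStart starting [RigidTransform-class].
#' @param config a [RegistrationConfig-class].
#' @return list with \code{transform} (accumulated), \code{rms} (objective at
#'   that transform), \code{iterations}, and \code{trace} (objective per
#'   iteration, evaluated before each estimation step).
#' @export
icpInnerLoop <- function(floating, reference, tStart = rigidTransform(),
                         config = registrationConfig()) {
  .checkRegistrationInputs(floating, reference)
  fp <- coords(floating)
  rp <- coords(reference)
  tf <- tStart
  ev <- evaluateObjective(fp, rp, tf, config)
  trace <- ev$rms
  iters <- 0L
  while (iters < config@maxInnerIterations) {
    w <- if (config@weightedEstimation) ev$weight else rep(1, length(ev$weight))
    step <- estimateRigidTransform(ev$moved, rp[ev$index, , drop = FALSE], w)
    tf <- composeTransforms(step, tf)
    iters <- iters + 1L
    evNew <- evaluateObjective(fp, rp, tf, config)
    trace <- c(trace, evNew$rms)
    done <- abs(ev$rms - evNew$rms) < config@innerDeltaTol
    ev <- evNew
    if (done) break
  }
  list(transform = tf, rms = ev$rms, iterations = iters, trace = trace)
}

.resolveThreshold <- function(config, reference) {
  if (is.na(config@rmsThreshold)) 1e-4 * bboxDiagonal(reference)
  else config@rmsThreshold
}

#' Improved-ICP registration
#'
#' The full I-ICP outer loop. Each round runs an inner ICP from the current
#' restart point; if its objective beats the best so far, the result is
#' accepted as the new best. Then the stop condition is checked (objective
#' below threshold, or round budget exhausted), and otherwise the
#' perturbation stage proposes a restart: gamma is the componentwise
#' parameter difference between the round's starting transform and its
#' converged result (the step the search just took), each of the six
#' parameters of the best transform receives an independent parabolic jump
#' within \code{+/- alpha * gamma_k}, and (optionally) a golden-section
#' search along the best-to-proposal segment in parameter space refines the
#' restart point within the proposal's neighbourhood (the segment interval
#' \code{[gsLower, gsUpper]} with default \code{gsLower = 0.5} excludes the
#' already-explored region near the incumbent). The range factor alpha
#' expands geometrically while rounds fail to improve and resets on success.
#' The best transform ever seen is always retained and returned. Restart
#' rounds whose correspondences degenerate (a wild jump matching everything
#' to one corner of the reference) count as failed rounds; a degenerate
#' first round from the user's own starting transform still raises an
#' error.
#'
#' @param floating [PointCloud-class] to be moved onto \code{reference}.
#' @param reference fixed [PointCloud-class].
#' @param config a [RegistrationConfig-class].
#' @return A [RegistrationResult-class].
#' @examples
#' case <- makeRegistrationCase(nReference = 300, nFloating = 80,
#'                              rotationDeg = c(10, 5, 8),
#'                              translationMm = c(20, 10, 5),
#'                              noiseSigmaMm = 0, outlierFraction = 0,
#'                              overlapFraction = 1, seed = 1)
#' res <- registerIICP(case@floating, case@reference,
#'                     registrationConfig(seed = 1))
#' bestRMS(res)
#' @export
registerIICP <- function(floating, reference,
                         config = registrationConfig()) {
  .checkRegistrationInputs(floating, reference)
  threshold <- .resolveThreshold(config, reference)
  fp <- coords(floating)
  rp <- coords(reference)
  diag_ <- bboxDiagonal(reference)
  jitter <- c(rep(config@jitterRotDeg * pi / 180, 3),
              rep(config@jitterTransFrac * diag_, 3))

  withSeed(config@seed, {
    tStart <- switch(config@coarseInit,
                     none = rigidTransform(),
                     centroid_pca = coarseAlignCentroidPCA(floating, reference))
    best <- tStart
    bestEv <- evaluateObjective(fp, rp, best, config)
    bestRMS <- bestEv$rms
    trace <- bestRMS
    state <- newPerturbationState(config)
    innerTotal <- 0L
    perturbRounds <- 0L
    reason <- "max_rounds"
    restart <- tStart
    gamma <- rep(0, 6)

    for (k in seq_len(config@maxOuterRounds)) {
      roundStart <- restart
      inner <- if (k == 1L) {
        icpInnerLoop(floating, reference, restart, config)
      } else {
        # a wild restart can degenerate; count it as a failed round
        tryCatch(icpInnerLoop(floating, reference, restart, config),
                 error = function(e) NULL)
      }
      if (!is.null(inner)) {
        innerTotal <- innerTotal + inner$iterations
        # gamma of Eq.-(7) form: the step this round's search took
        gamma <- tryCatch(transformDifference(roundStart, inner$transform),
                          error = function(e) rep(0, 6))  # gimbal-locked
      } else gamma <- rep(0, 6)
      improved <- !is.null(inner) && inner$rms < bestRMS
      if (improved) {
        best <- inner$transform
        bestRMS <- inner$rms
        trace <- c(trace, bestRMS)
      }
      state <- updateAlpha(state, improved, config)

      # stop condition first, then perturb
      if (bestRMS < threshold) {
        reason <- "threshold"
        break
      }
      if (k == config@maxOuterRounds) break

      if (!config@perturbation) {
        if (!improved) break  # deterministic restart from best cannot change
        restart <- best
        next
      }

      restart <- tryCatch({
        proposal <- proposePerturbedTransform(best, gamma, state$alpha, jitter)
        if (config@goldenSection) {
          p0 <- unname(toParameters(best))
          p1 <- unname(toParameters(proposal))
          fseg <- function(s) {
            p <- p0 + s * (p1 - p0)
            if (abs(abs(wrapAngle(p[2])) - pi / 2) < 1e-6) return(Inf)
            evaluateObjective(fp, rp, fromParameters(p), config)$rms
          }
          gs <- goldenSectionMinimize(
            fseg, config@gsLower, config@gsUpper,
            tol = config@gsTolFrac * (config@gsUpper - config@gsLower),
            maxEvals = config@gsMaxEvals)
          fromParameters(p0 + gs$minimum * (p1 - p0))
        } else proposal
      }, error = function(e) {
        # gimbal-locked best or pathological gamma: restart from a small
        # rotation applied to the best transform instead
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        th <- stats::runif(1, 0.5, 2) * pi / 180
        K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
                    3, 3)
        R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
        composeTransforms(rigidTransform(R), best)
      })
      perturbRounds <- perturbRounds + 1L
    }

    new("RegistrationResult", transform = best, bestRMS = bestRMS,
        rmsTrace = trace, innerIterationsTotal = innerTotal,
        perturbationRounds = perturbRounds, convergedReason = reason,
        seed = config@seed, config = config)
  })
}

#' Classic point-to-point ICP baseline
#'
#' Identical to [registerIICP()] with uniform weighting and both the
#' perturbation stage and the golden-section refinement disabled: one inner
#' ICP run from the starting transform, accepted if it improves on the
#' starting evaluation. This is the traditional algorithm whose sensitivity
#' to the starting position motivates the improved variant.
#'
#' @inheritParams registerIICP
#' @return A [RegistrationResult-class].
#' @export
registerICP <- function(floating, reference,
                        config = registrationConfig()) {
  cfg <- config
  cfg@weighting <- "uniform"
  cfg@perturbation <- FALSE
  cfg@goldenSection <- FALSE
  registerIICP(floating, reference, cfg)
}

#' Coarse alignment by centroids and principal axes
#'
#' Rough initializer: translates centroids onto each other and rotates the
#' floating cloud's principal axes (eigenvectors of the coordinate
#' covariance, ordered by decreasing eigenvalue) onto the reference's. Axis
#' signs are disambiguated by matching the sign of the third moment of the
#' projections; the final axis is chosen to make the rotation proper.
#'
#' @param floating,reference [PointCloud-class] objects.
#' @return A [RigidTransform-class] mapping floating roughly onto reference.
#' @export
coarseAlignCentroidPCA <- function(floating, reference) {
  axesOf <- function(co) {
    c0 <- colMeans(co)
    cc <- sweep(co, 2, c0)
    eg <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
    V <- eg$vectors
    for (k in 1:3) {
      m3 <- mean((cc %*% V[, k])^3)
      if (m3 < 0) V[, k] <- -V[, k]
    }
    if (det(V) < 0) V[, 3] <- -V[, 3]
    list(center = c0, axes = V)
  }
  f <- axesOf(coords(floating))
  r <- axesOf(coords(reference))
  R <- r$axes %*% t(f$axes)
  rigidTransform(R, r$center - as.vector(R %*% f$center))
}
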