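# S4 classes for clouds, transforms, correspondences and results.
# Coordinates are millimetres everywhere; no unit conversion happens on I/O.

.EMPTY_MARKERS <- data.frame(label = character(0), x = numeric(0),
                             y = numeric(0), z = numeric(0),
                             stringsAsFactors = FALSE)

#' PointCloud: an ordered set of 3-D points with optional labelled markers
#'
#' Coordinates are in millimetres. Markers are labelled fiducial points used
#' for evaluation only (never for fitting); labels must be unique.
#'
#' @slot coords numeric matrix, one row per point, columns x, y, z (mm).
#' @slot markers data.frame with columns \code{label, x, y, z}; may be empty.
#' @slot source character scalar provenance string (may be empty).
#'
#' @seealso [PointCloud()], [coords()], [markers()]
#' @export
setClass("PointCloud",
  representation(coords = "matrix", markers = "data.frame",
                 source = "character"),
  prototype(coords = matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("x", "y", "z"))),
            markers = .EMPTY_MARKERS, source = character(0)))

setValidity("PointCloud", function(object) {
  msgs <- character(0)
  co <- object@coords
  if (!is.numeric(co) || ncol(co) != 3)
    msgs <- c(msgs, "coords must be a numeric matrix with 3 columns")
  else {
    if (nrow(co) < 1) msgs <- c(msgs, "point cloud must contain at least one point")
    if (!all(is.finite(co))) msgs <- c(msgs, "all coordinates must be finite")
  }
  mk <- object@markers
  if (!all(c("label", "x", "y", "z") %in% names(mk)))
    msgs <- c(msgs, "markers must have columns label, x, y, z")
  else if (nrow(mk) > 0) {
    if (anyDuplicated(mk$label)) msgs <- c(msgs, "marker labels must be unique")
    if (!all(is.finite(as.matrix(mk[, c("x", "y", "z")]))))
      msgs <- c(msgs, "marker coordinates must be finite")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PointCloud
#'
#' @param coords numeric matrix (or coercible) with one row per point and
#'   three columns (x, y, z) in millimetres.
#' @param markers optional data.frame with columns \code{label, x, y, z}.
#' @param source optional provenance string.
#' @return A [PointCloud-class] object.
#' @examples
#' pc <- PointCloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' nPoints(pc)
#' @export
PointCloud <- function(coords, markers = NULL, source = character(0)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  if (is.null(markers)) markers <- .EMPTY_MARKERS
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (nrow(markers) > 0) {
    markers$label <- as.character(markers$label)
    markers <- markers[, c("label", "x", "y", "z")]
  } else markers <- .EMPTY_MARKERS
  rownames(markers) <- NULL
  new("PointCloud", coords = coords, markers = markers,
      source = as.character(source))
}

#' RigidTransform: a proper rotation plus translation
#'
#' Maps a point p to \code{rotation \%*\% p + translation}. The rotation must
#' be proper orthonormal (no reflection, shear or scale); translation is in
#' millimetres.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric length-3 vector (mm).
#'
#' @seealso [rigidTransform()], [applyTransform()], [composeTransforms()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

.ROT_TOL <- 1e-9

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msgs <- character(0)
  if (!is.numeric(R) || !all(dim(R) == c(3, 3)))
    return("rotation must be a 3x3 numeric matrix")
  if (length(object@translation) != 3 || !all(is.finite(object@translation)))
    msgs <- c(msgs, "translation must be a finite length-3 vector")
  if (!all(is.finite(R)))
    return(c(msgs, "rotation must be finite"))
  if (max(abs(crossprod(R) - diag(3))) > .ROT_TOL)
    msgs <- c(msgs, "rotation is not orthonormal (within 1e-9)")
  if (abs(det(R) - 1) > .ROT_TOL)
    msgs <- c(msgs, "rotation determinant is not +1 (reflection/shear is not rigid)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RigidTransform
#'
#' @param rotation 3x3 proper orthonormal matrix (default identity).
#' @param translation numeric length-3 translation in mm (default zero).
#' @return A [RigidTransform-class] object.
#' @examples
#' rigidTransform(diag(3), c(10, 0, 0))
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  storage.mode(rotation) <- "double"
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' CorrespondenceSet: nearest-reference matches for every floating point
#'
#' One entry per floating point: the index of its nearest reference point,
#' the Euclidean distance (mm), and — once assigned — the median-based weight
#' delta in (0, 1]. Many floating points may share one reference point; the
#' weighting exists precisely to damp the error such pile-ups accumulate.
#'
#' @slot refIndex integer vector of nearest reference indices (1-based).
#' @slot distance numeric vector of match distances (mm).
#' @slot weight numeric vector of weights in (0, 1]; length 0 until assigned.
#' @slot medianDistance numeric scalar (mm); length 0 until computed.
#' @export
setClass("CorrespondenceSet",
  representation(refIndex = "integer", distance = "numeric",
                 weight = "numeric", medianDistance = "numeric"))

setValidity("CorrespondenceSet", function(object) {
  msgs <- character(0)
  n <- length(object@refIndex)
  if (length(object@distance) != n)
    msgs <- c(msgs, "distance must have one entry per pair")
  if (any(object@distance < 0)) msgs <- c(msgs, "distances must be non-negative")
  if (length(object@weight) > 0) {
    if (length(object@weight) != n)
      msgs <- c(msgs, "weight must have one entry per pair")
    if (any(object@weight <= 0 | object@weight > 1))
      msgs <- c(msgs, "weights must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' RegistrationConfig: parameters controlling ICP / I-ICP runs
#'
#' @slot rmsThreshold stop threshold on the weighted RMS objective (mm);
#'   \code{NA} means auto: 1e-4 times the reference bounding-box diagonal.
#' @slot maxOuterRounds maximum number of outer recursions k.
#' @slot maxInnerIterations cap on inner ICP iterations per round.
#' @slot innerDeltaTol inner convergence tolerance on the objective (mm).
#' @slot weighting "median" (I-ICP weights) or "uniform" (classic ICP).
#' @slot medianRule "index" (sorted 1-based index N/2 even, (N+1)/2 odd) or
#'   "midpoint" (conventional averaged midpoint).
#' @slot objective "weighted_mean" (the printed (1/N) sum delta*d) or "rms"
#'   (true root-mean-square variant).
#' @slot weightedEstimation logical; if TRUE weights also shape the
#'   least-squares transform estimate, not only the objective.
#' @slot perturbation logical; enable the stochastic perturbation stage.
#' @slot goldenSection logical; refine the restart point by golden-section
#'   search along the best-to-proposal segment in parameter space.
#' @slot alphaStart,alphaFactor,alphaMax perturbation-range schedule: alpha
#'   starts at alphaStart, multiplies by alphaFactor on each round without
#'   improvement, resets on improvement, capped at alphaMax.
#' @slot jitterRotDeg,jitterTransFrac floors applied to zero components of
#'   gamma: degrees per rotation axis and fraction of the reference
#'   bounding-box diagonal per translation axis.
#' @slot gsTolFrac golden-section interval tolerance as a fraction of the
#'   initial interval width.
#' @slot gsMaxEvals cap on objective evaluations per golden-section search.
#' @slot gsLower,gsUpper search interval in segment coordinates (0 = current
#'   best, 1 = perturbed proposal; slight extrapolation beyond both ends).
#' @slot seed integer master seed for all stochastic draws.
#' @slot coarseInit "none" or "centroid_pca".
#' @seealso [registrationConfig()]
#' @export
setClass("RegistrationConfig",
  representation(rmsThreshold = "numeric", maxOuterRounds = "integer",
                 maxInnerIterations = "integer", innerDeltaTol = "numeric",
                 weighting = "character", medianRule = "character",
                 objective = "character", weightedEstimation = "logical",
                 perturbation = "logical", goldenSection = "logical",
                 alphaStart = "numeric", alphaFactor = "numeric",
                 alphaMax = "numeric", jitterRotDeg = "numeric",
                 jitterTransFrac = "numeric", gsTolFrac = "numeric",
                 gsMaxEvals = "integer", gsLower = "numeric",
                 gsUpper = "numeric", seed = "integer",
                 coarseInit = "character"))

setValidity("RegistrationConfig", function(object) {
  msgs <- character(0)
  if (!is.na(object@rmsThreshold) && object@rmsThreshold <= 0)
    msgs <- c(msgs, "rmsThreshold must be positive (or NA for auto)")
  if (object@maxOuterRounds < 1L || object@maxInnerIterations < 1L)
    msgs <- c(msgs, "iteration caps must be >= 1")
  if (object@innerDeltaTol <= 0) msgs <- c(msgs, "innerDeltaTol must be positive")
  if (!object@weighting %in% c("median", "uniform"))
    msgs <- c(msgs, "weighting must be 'median' or 'uniform'")
  if (!object@medianRule %in% c("index", "midpoint"))
    msgs <- c(msgs, "medianRule must be 'index' or 'midpoint'")
  if (!object@objective %in% c("weighted_mean", "rms"))
    msgs <- c(msgs, "objective must be 'weighted_mean' or 'rms'")
  if (object@alphaStart < 1 || object@alphaMax < object@alphaStart ||
      object@alphaFactor <= 1)
    msgs <- c(msgs, "alpha schedule requires alphaStart >= 1, alphaFactor > 1, alphaMax >= alphaStart")
  if (object@gsTolFrac <= 0 || object@gsMaxEvals < 4L)
    msgs <- c(msgs, "golden-section tolerance must be positive and gsMaxEvals >= 4")
  if (object@gsLower >= object@gsUpper)
    msgs <- c(msgs, "gsLower must be below gsUpper")
  if (!object@coarseInit %in% c("none", "centroid_pca"))
    msgs <- c(msgs, "coarseInit must be 'none' or 'centroid_pca'")
  if (length(msgs)) msgs else TRUE
})

#' RegistrationResult: output of a registration run
#'
#' @slot transform best [RigidTransform-class] found (maps floating into the
#'   reference frame).
#' @slot bestRMS final value of the weighted RMS objective (mm).
#' @slot rmsTrace objective values of the accepted bests, starting with the
#'   evaluation at the starting transform; non-increasing by construction.
#' @slot innerIterationsTotal total inner ICP iterations across all rounds.
#' @slot perturbationRounds number of perturbation restarts performed.
#' @slot convergedReason "threshold" or "max_rounds".
#' @slot seed master seed used.
#' @slot config the resolved [RegistrationConfig-class].
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform", bestRMS = "numeric",
                 rmsTrace = "numeric", innerIterationsTotal = "integer",
                 perturbationRounds = "integer", convergedReason = "character",
                 seed = "integer", config = "RegistrationConfig"))

setValidity("RegistrationResult", function(object) {
  msgs <- character(0)
  tr <- object@rmsTrace
  if (length(tr) > 1 && any(diff(tr) > 1e-12))
    msgs <- c(msgs, "accepted-best RMS trace must be non-increasing")
  if (!object@convergedReason %in% c("threshold", "max_rounds"))
    msgs <- c(msgs, "convergedReason must be 'threshold' or 'max_rounds'")
  if (length(msgs)) msgs else TRUE
})

#' TREReport: target registration error at labelled markers
#'
#' Per-marker TRE (Euclidean distance between the known validation point and
#' the registered floating point), signed per-axis errors, and per-axis
#' averages of absolute errors — the layout used for fiducial evaluation in
#' image-guided surgery.
#'
#' @slot tre named numeric vector of per-marker TRE (mm).
#' @slot axisErrors data.frame \code{label, x, y, z} of signed errors
#'   (registered minus validation), mm.
#' @slot axisAverages numeric length-3 vector of per-axis means of absolute
#'   errors (mm).
#' @export
setClass("TREReport",
  representation(tre = "numeric", axisErrors = "data.frame",
                 axisAverages = "numeric"))

setValidity("TREReport", function(object) {
  msgs <- character(0)
  n <- length(object@tre)
  if (nrow(object@axisErrors) != n)
    msgs <- c(msgs, "axisErrors must have one row per marker")
  else if (n > 0) {
    e <- as.matrix(object@axisErrors[, c("x", "y", "z")])
    if (max(abs(sqrt(rowSums(e^2)) - object@tre)) > 1e-9)
      msgs <- c(msgs, "tre must equal the Euclidean norm of per-axis errors")
    if (max(abs(colMeans(abs(e)) - object@axisAverages)) > 1e-9)
      msgs <- c(msgs, "axisAverages must be means of absolute per-axis errors")
  }
  if (length(msgs)) msgs else TRUE
})

#' RegistrationCase: a synthetic registration problem with known truth
#'
#' @slot reference dense surface [PointCloud-class] (the "CT surface") with
#'   five labelled markers at fixed surface features.
#' @slot floating sparser, pre-displaced scan [PointCloud-class] (noise and
#'   outliers included) carrying the same marker labels in its own frame.
#' @slot groundTruth [RigidTransform-class] mapping the floating cloud onto
#'   the reference.
#' @slot generatorParams list echoing every generator parameter incl. seed.
#' @export
setClass("RegistrationCase",
  representation(reference = "PointCloud", floating = "PointCloud",
                 groundTruth = "RigidTransform", generatorParams = "list"))

setValidity("RegistrationCase", function(object) {
  mr <- object@reference@markers
  mf <- object@floating@markers
  if (nrow(mr) < 5 || nrow(mf) < 5)
    return("a registration case carries at least five markers in each frame")
  if (!setequal(mr$label, mf$label))
    return("marker labels must correspond one-to-one between frames")
  TRUE
})
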