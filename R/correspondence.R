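# Nearest-neighbour correspondences and the median-based weighting that
# defines the I-ICP objective. Matching is point-to-point and many-to-one:
# several floating points may land on the same reference point — exactly the
# situation the weights are designed to damp.

#' Nearest-reference correspondences for every floating point
#'
#' For each floating point, the reference point minimizing the Euclidean
#' distance; exact search over a KD-tree with ties broken by the smallest
#' reference index. Weights are left unset.
#'
#' @param floating,reference [PointCloud-class] objects (or n x 3 matrices).
#' @return A [CorrespondenceSet-class] with one pair per floating point.
#' @export
nearestCorrespondences <- function(floating, reference) {
  fp <- if (is(floating, "PointCloud")) coords(floating) else as.matrix(floating)
  rp <- if (is(reference, "PointCloud")) coords(reference) else as.matrix(reference)
  if (nrow(fp) < 1 || nrow(rp) < 1) stop("empty point cloud")
  nn <- .nn_kdtree(rp, fp)
  new("CorrespondenceSet", refIndex = nn$index, distance = nn$distance,
      weight = numeric(0), medianDistance = numeric(0))
}

#' Complete a correspondence set with median-based weights
#'
#' Computes the group median of the match distances ([sortedMedian()]) and
#' the weights ([assignWeights()]) and stores both on the set.
#'
#' @param cs a [CorrespondenceSet-class] from [nearestCorrespondences()].
#' @param rule median rule, "index" (default) or "midpoint".
#' @return the completed [CorrespondenceSet-class].
#' @export
weightCorrespondences <- function(cs, rule = c("index", "midpoint")) {
  stopifnot(is(cs, "CorrespondenceSet"))
  med <- sortedMedian(cs@distance, rule = match.arg(rule))
  cs@medianDistance <- med
  cs@weight <- assignWeights(cs@distance, med)
  validObject(cs)
  cs
}

#' Median of a distance group by the sorted-index rule
#'
#' Sorts ascending and returns the element at 1-based position N/2 when N is
#' even and (N+1)/2 when N is odd — the literal index rule, not the
#' conventional averaged midpoint. The conventional midpoint average is
#' available with \code{rule = "midpoint"}.
#'
#' @param distances non-empty numeric vector of non-negative distances (mm).
#' @param rule "index" (default) or "midpoint".
#' @return scalar median distance (mm).
#' @examples
#' sortedMedian(c(5, 1, 3))     # 3
#' sortedMedian(c(4, 1, 3, 2))  # 2 (index rule), not 2.5
#' @export
sortedMedian <- function(distances, rule = c("index", "midpoint")) {
  rule <- match.arg(rule)
  n <- length(distances)
  if (n == 0) stop("cannot take the median of an empty distance group")
  if (any(distances < 0)) stop("distances must be non-negative")
  if (rule == "midpoint") return(stats::median(distances))
  s <- sort(distances)
  k <- if (n %% 2 == 0) n %/% 2 else (n + 1) %/% 2
  s[k]
}

# Weight floor used when the median distance is 0 but a distance is not:
# keeps every weight positive so the weighted estimate stays defined after
# perfect convergence of half the points.
.WEIGHT_FLOOR <- 1e-6

#' Median-based correspondence weights
#'
#' \eqn{\delta_i = 1} when \eqn{d_i \le m} and \eqn{\delta_i = m / d_i}
#' otherwise, where m is the group median: points matched farther than the
#' median — typically wrong matches from non-overlapping regions — are
#' down-weighted in proportion. At \eqn{d = m} both branches give 1, so the
#' function is continuous. When m = 0, distances of 0 get weight 1 and
#' positive distances get the floor 1e-6.
#'
#' @param distances non-negative numeric vector (mm).
#' @param medianDistance the group median from [sortedMedian()] (mm).
#' @return numeric vector of weights in (0, 1].
#' @export
assignWeights <- function(distances, medianDistance) {
  if (any(distances < 0)) stop("distances must be non-negative")
  if (medianDistance < 0) stop("median distance must be non-negative")
  w <- rep(1, length(distances))
  far <- distances > medianDistance
  if (any(far)) w[far] <- pmax(medianDistance / distances[far], .WEIGHT_FLOOR)
  w
}

#' The weighted RMS objective
#'
#' The registration objective \eqn{(1/N_F) \sum_i \delta_i d_i} — a weighted
#' arithmetic mean of match distances, kept under its field name "RMS". A
#' true root-mean-square variant \eqn{\sqrt{(1/N_F)\sum_i \delta_i d_i^2}}
#' is available with \code{objective = "rms"} but is not the default.
#'
#' @param distances,weights numeric vectors of equal length.
#' @param objective "weighted_mean" (default) or "rms".
#' @return scalar objective value (mm).
#' @export
weightedRMS <- function(distances, weights,
                        objective = c("weighted_mean", "rms")) {
  objective <- match.arg(objective)
  if (length(distances) != length(weights))
    stop("distances and weights must have equal length")
  if (objective == "rms")
    sqrt(sum(weights * distances^2) / length(distances))
  else
    sum(weights * distances) / length(distances)
}

# One full evaluation of the objective at a transform: move the floating
# cloud, match, weight, score. The workhorse shared by the inner loop, the
# golden-section refinement and the result invariant.
evaluateObjective <- function(floatCoords, refCoords, transform, config) {
  moved <- applyTransform(transform, floatCoords)
  nn <- .nn_kdtree(refCoords, moved)
  d <- nn$distance
  if (config@weighting == "uniform") {
    w <- rep(1, length(d))
    med <- NA_real_
  } else {
    med <- sortedMedian(d, rule = config@medianRule)
    w <- assignWeights(d, med)
  }
  list(rms = weightedRMS(d, w, objective = config@objective),
       distance = d, weight = w, index = nn$index, median = med,
       moved = moved)
}
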