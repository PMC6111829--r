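# Generics and accessors. Slots are never touched directly by user code.

#' Extract point coordinates
#' @param x a [PointCloud-class]
#' @return numeric matrix with columns x, y, z (mm).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "PointCloud", function(x) x@coords)

#' Extract labelled markers
#' @param x a [PointCloud-class]
#' @return data.frame with columns label, x, y, z.
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname markers
#' @export
setMethod("markers", "PointCloud", function(x) x@markers)

#' Number of points in a cloud
#' @param x a [PointCloud-class]
#' @return integer point count.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "PointCloud", function(x) nrow(x@coords))

#' Rotation matrix of a rigid transform
#' @param x a [RigidTransform-class]
#' @return 3x3 orthonormal matrix.
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))

#' @rdname rotation
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)

#' Translation vector of a rigid transform
#' @param x a [RigidTransform-class]
#' @return numeric length-3 vector (mm).
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @rdname translation
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)

#' 4x4 homogeneous matrix view of a rigid transform
#' @param x a [RigidTransform-class]
#' @return 4x4 row-major homogeneous matrix.
#' @export
setGeneric("asMatrix", function(x) standardGeneric("asMatrix"))

#' @rdname asMatrix
#' @export
setMethod("asMatrix", "RigidTransform", function(x) {
  m <- diag(4)
  m[1:3, 1:3] <- x@rotation
  m[1:3, 4] <- x@translation
  m
})

#' Best transform of a registration result
#' @param x a [RegistrationResult-class]
#' @return the best [RigidTransform-class] found.
#' @export
setGeneric("resultTransform", function(x) standardGeneric("resultTransform"))

#' @rdname resultTransform
#' @export
setMethod("resultTransform", "RegistrationResult", function(x) x@transform)

#' Final objective value of a registration result
#' @param x a [RegistrationResult-class]
#' @return weighted RMS objective at the best transform (mm).
#' @export
setGeneric("bestRMS", function(x) standardGeneric("bestRMS"))

#' @rdname bestRMS
#' @export
setMethod("bestRMS", "RegistrationResult", function(x) x@bestRMS)

#' Accepted-best objective trace of a registration run
#' @param x a [RegistrationResult-class]
#' @return numeric vector of accepted best objective values (non-increasing).
#' @export
setGeneric("rmsTrace", function(x) standardGeneric("rmsTrace"))

#' @rdname rmsTrace
#' @export
setMethod("rmsTrace", "RegistrationResult", function(x) x@rmsTrace)

#' Per-marker target registration errors
#' @param x a [TREReport-class]
#' @return named numeric vector of per-marker TRE (mm).
#' @export
setGeneric("markerTRE", function(x) standardGeneric("markerTRE"))

#' @rdname markerTRE
#' @export
setMethod("markerTRE", "TREReport", function(x) x@tre)

# ---- show methods -----------------------------------------------------------

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud with %d points", nrow(object@coords)))
  if (nrow(object@markers) > 0)
    cat(sprintf(" and %d markers (%s)", nrow(object@markers),
                paste(utils::head(object@markers$label, 5), collapse = ", ")))
  cat("\n")
  rng <- apply(object@coords, 2, range)
  cat(sprintf("  extent (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  if (length(object@source)) cat("  source:", object@source, "\n")
})

setMethod("show", "RigidTransform", function(object) {
  p <- tryCatch(toParameters(object), error = function(e) NULL)
  cat("RigidTransform\n")
  if (!is.null(p)) {
    cat(sprintf("  rotation (deg, extrinsic XYZ): %.3f %.3f %.3f\n",
                p[1] * 180 / pi, p[2] * 180 / pi, p[3] * 180 / pi))
  }
  cat(sprintf("  translation (mm): %.3f %.3f %.3f\n",
              object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "RegistrationResult", function(object) {
  cat(sprintf("RegistrationResult (%s weighting, seed %d)\n",
              object@config@weighting, object@seed))
  cat(sprintf("  best objective: %.6g mm after %d accepted bests\n",
              object@bestRMS, length(object@rmsTrace)))
  cat(sprintf("  inner iterations: %d, perturbation restarts: %d, stopped: %s\n",
              object@innerIterationsTotal, object@perturbationRounds,
              object@convergedReason))
  show(object@transform)
})

setMethod("show", "TREReport", function(object) {
  cat(sprintf("TREReport over %d markers\n", length(object@tre)))
  print(as.data.frame(object))
  cat(sprintf("  per-axis mean |error| (mm): x %.3f  y %.3f  z %.3f\n",
              object@axisAverages[1], object@axisAverages[2],
              object@axisAverages[3]))
  cat(sprintf("  mean TRE: %.3f mm\n", mean(object@tre)))
})

setMethod("show", "RegistrationCase", function(object) {
  cat("RegistrationCase\n  reference: ")
  show(object@reference)
  cat("  floating:  ")
  show(object@floating)
  cat("  ground truth: ")
  show(object@groundTruth)
})

#' Tabular view of a TRE report
#'
#' @param x a [TREReport-class]
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @return data.frame with label, signed per-axis errors and TRE (mm).
#' @export
as.data.frame.TREReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(label = x@axisErrors$label, x = x@axisErrors$x,
             y = x@axisErrors$y, z = x@axisErrors$z, tre = unname(x@tre),
             stringsAsFactors = FALSE)
}
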