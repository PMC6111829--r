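# Synthetic scan-to-surface registration cases with known ground truth.
# The surfaces are closed star-shaped parametric shells — an ellipsoid at
# head-like scale, or a near-symmetric sphere — decorated with Gaussian
# bumps of distinct amplitude at fixed latitudes. The asymmetric bumps play
# the role of facial features: they defeat spurious symmetry solutions and
# give the five markers reproducible "anatomical" loci across seeds.

# Fixed feature (bump) definitions per surface kind: direction given as
# latitude/longitude in degrees, amplitude in mm, angular width in radians.
.SURFACES <- list(
  head_ellipsoid = list(
    semi = c(100, 75, 90),  # -> bounding box ~200 x 150 x 180 mm
    bumps = data.frame(
      lat = c(40, 10, -30, 60, -10),
      lon = c(20, 150, 260, 200, 60),
      amp = c(14, 9, 12, 7, 10),
      width = c(0.35, 0.30, 0.40, 0.25, 0.30))),
  bumpy_sphere = list(
    semi = c(85, 75, 65),  # mildly anisotropic near-sphere
    bumps = data.frame(
      lat = c(40, 10, -30, 60, -10),
      lon = c(20, 150, 260, 200, 60),
      amp = c(14, 9, 12, 7, 10),
      width = c(0.35, 0.30, 0.40, 0.25, 0.30))))

.unitFromLatLon <- function(latDeg, lonDeg) {
  la <- latDeg * pi / 180
  lo <- lonDeg * pi / 180
  cbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

# Radius of the surface along unit directions u (rows): ellipsoidal radius
# plus Gaussian bumps in angular distance from each bump centre.
.surfaceRadius <- function(u, kind) {
  spec <- .SURFACES[[kind]]
  s <- spec$semi
  r0 <- 1 / sqrt((u[, 1] / s[1])^2 + (u[, 2] / s[2])^2 + (u[, 3] / s[3])^2)
  bc <- .unitFromLatLon(spec$bumps$lat, spec$bumps$lon)
  for (b in seq_len(nrow(bc))) {
    cosang <- pmin(1, pmax(-1, u %*% bc[b, ]))
    ang <- acos(cosang)
    r0 <- r0 + spec$bumps$amp[b] * exp(-ang^2 / (2 * spec$bumps$width[b]^2))
  }
  as.vector(r0)
}

# Implicit surface residual ||p|| - radius(p/||p||); zero for on-surface points.
.surfaceResidual <- function(points, kind) {
  nr <- sqrt(rowSums(points^2))
  nr - .surfaceRadius(points / nr, kind)
}

.surfaceMarkers <- function(kind) {
  spec <- .SURFACES[[kind]]
  u <- .unitFromLatLon(spec$bumps$lat, spec$bumps$lon)
  r <- .surfaceRadius(u, kind)
  data.frame(label = paste0("M", seq_len(nrow(u))),
             x = u[, 1] * r, y = u[, 2] * r, z = u[, 3] * r,
             stringsAsFactors = FALSE)
}

#' Sample a synthetic closed surface
#'
#' Draws \code{nPoints} from a closed star-shaped surface: an ellipsoid at
#' head scale (bounding box roughly 200 x 150 x 180 mm) or a near-symmetric
#' sphere, each decorated with five Gaussian bumps of distinct amplitude at
#' fixed latitudes. Directions are sampled uniformly on the sphere;
#' generation is deterministic per seed. The five bump apexes are attached
#' as labelled markers M1..M5.
#'
#' @param kind "head_ellipsoid" or "bumpy_sphere".
#' @param nPoints number of surface points.
#' @param seed integer seed.
#' @return A [PointCloud-class] with five markers.
#' @export
makeSurfaceCloud <- function(kind = c("head_ellipsoid", "bumpy_sphere"),
                             nPoints = 2000L, seed = 1L) {
  kind <- match.arg(kind)
  if (nPoints < 1) stop("nPoints must be >= 1")
  withSeed(seed, {
    z <- stats::runif(nPoints, -1, 1)
    phi <- stats::runif(nPoints, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    u <- cbind(s * cos(phi), s * sin(phi), z)
    r <- .surfaceRadius(u, kind)
    PointCloud(u * r, markers = .surfaceMarkers(kind),
               source = sprintf("synthetic %s (seed %d)", kind, seed))
  })
}

#' Generate a registration case with known ground truth
#'
#' Emulates a single-view sensor scan of a CT-derived surface: the floating
#' cloud is a random subsample of a half-space crop of the reference cloud
#' (a depth sensor sees one side; the crop plane orientation is randomized
#' per seed), perturbed by per-axis Gaussian noise, with a fraction of points
#' replaced by uniform outliers in the bounding box, and finally pushed
#' through the inverse of the ground-truth transform so that registering it
#' back onto the reference recovers that transform. Markers ride along in
#' both frames (noise-free).
#'
#' Defaults reproduce the package's headline scenario: 2,000 reference and
#' 500 floating points, 70% overlap, 1 mm noise, 2% outliers, and a
#' displacement of 30 degrees about the (1,1,1) diagonal plus a 100 mm
#' translation along it.
#'
#' @param surfaceKind "head_ellipsoid" or "bumpy_sphere".
#' @param nReference,nFloating point counts.
#' @param rotationDeg extrinsic XYZ Euler angles of the ground-truth
#'   rotation, degrees.
#' @param translationMm ground-truth translation vector, mm.
#' @param noiseSigmaMm per-axis Gaussian noise sd, mm.
#' @param outlierFraction fraction of floating points replaced by uniform
#'   outliers, in \code{[0, 0.5)}.
#' @param overlapFraction fraction of the surface kept by the half-space
#'   crop, in \code{(0, 1]}.
#' @param seed integer seed.
#' @return A [RegistrationCase-class].
#' @export
makeRegistrationCase <- function(surfaceKind = c("head_ellipsoid",
                                                 "bumpy_sphere"),
                                 nReference = 2000L, nFloating = 500L,
                                 rotationDeg = axisAngleToEulerDeg(30, c(1, 1, 1)),
                                 translationMm = 100 * c(1, 1, 1) / sqrt(3),
                                 noiseSigmaMm = 1, outlierFraction = 0.02,
                                 overlapFraction = 0.7, seed = 1L) {
  surfaceKind <- match.arg(surfaceKind)
  if (overlapFraction <= 0 || overlapFraction > 1)
    stop("overlapFraction must lie in (0, 1]")
  if (outlierFraction < 0 || outlierFraction >= 0.5)
    stop("outlierFraction must lie in [0, 0.5)")
  if (noiseSigmaMm < 0) stop("noiseSigmaMm must be non-negative")

  reference <- makeSurfaceCloud(surfaceKind, nReference, seed)
  rp <- coords(reference)

  gt <- fromParameters(c(rotationDeg * pi / 180, translationMm))
  gtInv <- invertTransform(gt)

  floating <- withSeed(seed + 1L, {
    # half-space crop: keep the overlapFraction of points farthest along a
    # random viewing direction
    w <- stats::rnorm(3); w <- w / sqrt(sum(w^2))
    proj <- as.vector(rp %*% w)
    keep <- which(proj >= stats::quantile(proj, 1 - overlapFraction))
    if (length(keep) < nFloating)
      stop("not enough points in the cropped region; lower nFloating or raise overlapFraction")
    idx <- sample(keep, nFloating)
    pts <- rp[idx, , drop = FALSE]
    if (noiseSigmaMm > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, noiseSigmaMm),
                          ncol = 3)
    nOut <- round(outlierFraction * nFloating)
    outIdx <- integer(0)
    if (nOut > 0) {
      rng <- apply(rp, 2, range)
      out <- cbind(stats::runif(nOut, rng[1, 1], rng[2, 1]),
                   stats::runif(nOut, rng[1, 2], rng[2, 2]),
                   stats::runif(nOut, rng[1, 3], rng[2, 3]))
      outIdx <- sample(nFloating, nOut)
      pts[outIdx, ] <- out
    }
    list(cloud = applyTransform(gtInv,
           PointCloud(pts, markers = markers(reference),
                      source = sprintf("synthetic scan (seed %d)", seed))),
         sampleIndices = idx, outlierIndices = outIdx)
  })

  new("RegistrationCase", reference = reference,
      floating = floating$cloud, groundTruth = gt,
      generatorParams = list(surfaceKind = surfaceKind,
                             sampleIndices = floating$sampleIndices,
                             outlierIndices = floating$outlierIndices,
                             nReference = as.integer(nReference),
                             nFloating = as.integer(nFloating),
                             rotationDeg = rotationDeg,
                             translationMm = translationMm,
                             noiseSigmaMm = noiseSigmaMm,
                             outlierFraction = outlierFraction,
                             overlapFraction = overlapFraction,
                             seed = as.integer(seed)))
}

#' A certified local-minimum fixture
#'
#' A case engineered so classic ICP started from the identity stalls in a
#' locally optimal alignment: a near-symmetric bumpy sphere displaced by a
#' rotation well beyond the baseline's convergence basin. The property is
#' certified at generation time by running [registerICP()] and asserting a
#' ground-truth rotation error above 10 degrees; seeds are advanced until it
#' holds, and the accepted seed is recorded in the generator parameters.
#'
#' @param seed integer starting seed.
#' @param maxTries how many seeds to try before giving up.
#' @return A [RegistrationCase-class] whose generator parameters include
#'   \code{acceptedSeed} and \code{icpRotationErrorDeg}.
#' @export
localMinimumFixture <- function(seed = 1L, maxTries = 20L) {
  for (i in seq_len(maxTries)) {
    s <- as.integer(seed + (i - 1L) * 1000L)
    case <- makeRegistrationCase("bumpy_sphere", nReference = 500L,
                                 nFloating = 120L,
                                 rotationDeg = c(50, 50, 50),
                                 translationMm = 80 * c(1, 1, 1) / sqrt(3),
                                 noiseSigmaMm = 0, outlierFraction = 0,
                                 overlapFraction = 0.85, seed = s)
    res <- registerICP(case@floating, case@reference,
                       registrationConfig(seed = s))
    err <- rotationAngle(resultTransform(res), case@groundTruth)
    if (err > 10) {
      case@generatorParams$acceptedSeed <- s
      case@generatorParams$icpRotationErrorDeg <- err
      return(case)
    }
  }
  stop("no seed produced a certified local-minimum case within maxTries")
}

#' Write / read a registration case as a directory of standard files
#'
#' Materializes \code{reference.ply}, \code{floating.ply} (markers embedded
#' as PLY comments), \code{ground_truth.json}, \code{markers.csv} (both
#' frames) and \code{params.json}.
#'
#' @param case a [RegistrationCase-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory path.
#' @export
writeRegistrationCase <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePointCloud(case@reference, file.path(dir, "reference.ply"), "ply")
  writePointCloud(case@floating, file.path(dir, "floating.ply"), "ply")
  writeTransform(case@groundTruth, file.path(dir, "ground_truth.json"))
  mr <- markers(case@reference); mr$frame <- "reference"
  mf <- markers(case@floating); mf$frame <- "floating"
  utils::write.csv(rbind(mr, mf), file.path(dir, "markers.csv"),
                   row.names = FALSE)
  jsonlite::write_json(case@generatorParams, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeRegistrationCase
#' @export
readRegistrationCase <- function(dir) {
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  new("RegistrationCase",
      reference = readPointCloud(file.path(dir, "reference.ply")),
      floating = readPointCloud(file.path(dir, "floating.ply")),
      groundTruth = readTransform(file.path(dir, "ground_truth.json")),
      generatorParams = as.list(params))
}

#' Download the Stanford Bunny scan (convenience only)
#'
#' Fetches the classic reconstruction-benchmark mesh and extracts its
#' vertices as a point cloud. Requires network access; nothing in the
#' package depends on it — all tests run on generated surfaces.
#'
#' @param destdir directory to store the download.
#' @param url source archive URL.
#' @return A [PointCloud-class] of the bunny vertices.
#' @export
fetchBunny <- function(destdir = tempdir(),
                       url = "http://graphics.stanford.edu/pub/3Dscanrep/bunny.tar.gz") {
  tar <- file.path(destdir, "bunny.tar.gz")
  if (!file.exists(tar)) utils::download.file(url, tar, mode = "wb")
  utils::untar(tar, exdir = destdir)
  ply <- file.path(destdir, "bunny", "reconstruction", "bun_zipper.ply")
  if (!file.exists(ply)) stop("bunny archive did not contain the expected mesh")
  readPointCloud(ply, format = "ply")
}
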