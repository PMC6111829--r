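# Point-cloud and transform I/O. Units are millimetres throughout; no
# conversion happens on read or write. PLY support covers ASCII and
# binary-little-endian vertex data; other dialects are rejected with a clear
# error. Markers travel inside PLY/PCD files as comment-encoded lines and
# beside XYZ/CSV files as a labelled sidecar, so standard tools still read
# the files.

.PLY_SIZES <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.parseMarkerComment <- function(lines, tag) {
  pat <- paste0("^(comment|#)\\s+", tag, "\\s+")
  ml <- grep(pat, lines, value = TRUE)
  if (!length(ml)) return(NULL)
  parts <- strsplit(sub(pat, "", ml), "\\s+")
  data.frame(label = vapply(parts, `[`, "", 1L),
             x = as.numeric(vapply(parts, `[`, "", 2L)),
             y = as.numeric(vapply(parts, `[`, "", 3L)),
             z = as.numeric(vapply(parts, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

.markerCommentLines <- function(markers, prefix) {
  if (is.null(markers) || nrow(markers) == 0) return(character(0))
  if (any(grepl("\\s", markers$label)))
    stop("marker labels must not contain whitespace for comment embedding")
  sprintf("%s marker %s %.17g %.17g %.17g", prefix, markers$label,
          markers$x, markers$y, markers$z)
}

.readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # read header lines byte-wise (the body may be binary)
  header <- character(0)
  repeat {
    line <- character(0)
    repeat {
      ch <- readBin(con, "raw", 1L)
      if (length(ch) == 0) stop("unexpected end of PLY header in ", path)
      if (ch == as.raw(10L)) break
      if (ch != as.raw(13L)) line <- c(line, rawToChar(ch))
    }
    line <- paste(line, collapse = "")
    header <- c(header, line)
    if (grepl("^end_header", line)) break
    if (length(header) > 10000) stop("malformed PLY header in ", path)
  }
  if (!grepl("^ply", header[1])) stop("not a PLY file: ", path)
  fmt <- grep("^format ", header, value = TRUE)
  if (!length(fmt)) stop("PLY file lacks a format line: ", path)
  fmt <- strsplit(fmt[1], "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY dialect '", fmt,
         "': only ascii and binary_little_endian are handled")

  # element/property structure; the vertex element must come first
  elemIdx <- grep("^element ", header)
  if (!length(elemIdx)) stop("PLY file declares no elements: ", path)
  firstElem <- strsplit(header[elemIdx[1]], "\\s+")[[1]]
  if (firstElem[2] != "vertex")
    stop("only PLY files whose first element is 'vertex' are supported")
  nVertex <- as.integer(firstElem[3])
  if (is.na(nVertex) || nVertex < 1) stop("empty point cloud in ", path)
  propEnd <- if (length(elemIdx) > 1) elemIdx[2] else length(header)
  propLines <- grep("^property ", header[elemIdx[1]:propEnd], value = TRUE)
  props <- do.call(rbind, lapply(strsplit(propLines, "\\s+"), function(p) {
    if (p[2] == "list")
      stop("list properties on the vertex element are not supported")
    data.frame(type = p[2], name = p[3], stringsAsFactors = FALSE)
  }))
  xyz <- match(c("x", "y", "z"), props$name)
  if (any(is.na(xyz))) stop("PLY vertex element lacks x/y/z properties: ", path)

  if (fmt == "ascii") {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    if (length(body) < nVertex)
      stop("PLY body has fewer rows than declared vertices in ", path)
    co <- matrix(NA_real_, nVertex, 3)
    for (i in seq_len(nVertex)) {
      f <- strsplit(trimws(body[i]), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(f[xyz]))
      if (length(f) < max(xyz) || any(is.na(v)))
        stop("malformed PLY vertex record at body line ", i, " of ", path)
      co[i, ] <- v
    }
  } else {
    sizes <- .PLY_SIZES[props$type]
    if (any(is.na(sizes))) stop("unknown PLY property type in ", path)
    stride <- sum(sizes)
    raw <- readBin(con, "raw", nVertex * stride)
    if (length(raw) < nVertex * stride)
      stop("PLY binary body shorter than declared in ", path)
    offsets <- c(0L, cumsum(sizes))[seq_along(sizes)]
    co <- matrix(NA_real_, nVertex, 3)
    for (k in 1:3) {
      p <- xyz[k]
      sz <- sizes[p]
      sel <- as.vector(outer(seq_len(sz),
                             (seq_len(nVertex) - 1L) * stride + offsets[p],
                             "+"))
      co[, k] <- readBin(raw[sel], "double", n = nVertex, size = sz,
                         endian = "little")
    }
  }
  PointCloud(co, markers = .parseMarkerComment(header, "marker"),
             source = path)
}

.writePLY <- function(cloud, path, binary = FALSE) {
  co <- coords(cloud)
  n <- nrow(co)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              .markerCommentLines(markers(cloud), "comment"),
              sprintf("element vertex %d", n),
              "property double x", "property double y", "property double z",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    writeBin(as.vector(t(co)), con, size = 8, endian = "little")
  } else {
    writeLines(sprintf("%.17g %.17g %.17g", co[, 1], co[, 2], co[, 3]),
               con, sep = "\n")
  }
}

.readPCD <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dataIdx <- grep("^DATA\\s", lines)
  if (!length(dataIdx)) stop("not a PCD file (no DATA line): ", path)
  if (!grepl("^DATA\\s+ascii", lines[dataIdx[1]]))
    stop("only DATA ascii PCD files are supported: ", path)
  header <- lines[seq_len(dataIdx[1])]
  fieldsLine <- grep("^FIELDS\\s", header, value = TRUE)
  if (!length(fieldsLine)) stop("PCD file lacks a FIELDS line: ", path)
  fields <- strsplit(fieldsLine[1], "\\s+")[[1]][-1]
  xyz <- match(c("x", "y", "z"), fields)
  if (any(is.na(xyz))) stop("PCD FIELDS lack x/y/z: ", path)
  body <- lines[-seq_len(dataIdx[1])]
  body <- body[nzchar(trimws(body)) & !grepl("^#", body)]
  if (!length(body)) stop("empty point cloud in ", path)
  co <- matrix(NA_real_, length(body), 3)
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f[xyz]))
    if (length(f) < max(xyz) || any(is.na(v)))
      stop("malformed PCD record at body line ", i, " of ", path)
    co[i, ] <- v
  }
  PointCloud(co, markers = .parseMarkerComment(header, "#"), source = path)
}

.writePCD <- function(cloud, path) {
  co <- coords(cloud)
  n <- nrow(co)
  lines <- c("# .PCD v0.7 - Point Cloud Data file format",
             .markerCommentLines(markers(cloud), "#"),
             "VERSION 0.7", "FIELDS x y z", "SIZE 8 8 8", "TYPE F F F",
             "COUNT 1 1 1", sprintf("WIDTH %d", n), "HEIGHT 1",
             "VIEWPOINT 0 0 0 1 0 0 0", sprintf("POINTS %d", n),
             "DATA ascii",
             sprintf("%.17g %.17g %.17g", co[, 1], co[, 2], co[, 3]))
  writeLines(lines, path)
}

.sidecarPath <- function(path) paste0(path, ".markers.csv")

.readXYZ <- function(path, sep = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", trimws(lines))]
  if (!length(lines)) stop("empty point cloud in ", path)
  if (is.null(sep)) sep <- if (grepl(",", lines[1])) "," else ""
  # tolerate a non-numeric header row in CSV exports
  firstVals <- suppressWarnings(as.numeric(
    strsplit(trimws(lines[1]), if (sep == ",") "," else "\\s+")[[1]]))
  if (all(is.na(firstVals)) && length(lines) > 1) lines <- lines[-1]
  co <- matrix(NA_real_, length(lines), 3)
  splitPat <- if (sep == ",") "\\s*,\\s*" else "\\s+"
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), splitPat)[[1]]
    v <- suppressWarnings(as.numeric(f[1:3]))
    if (length(f) < 3 || any(is.na(v)))
      stop("malformed coordinate record at line ", i, " of ", path)
    co[i, ] <- v
  }
  mk <- NULL
  side <- .sidecarPath(path)
  if (file.exists(side))
    mk <- utils::read.csv(side, stringsAsFactors = FALSE)
  PointCloud(co, markers = mk, source = path)
}

.writeXYZ <- function(cloud, path, sep = " ") {
  co <- coords(cloud)
  writeLines(sprintf(paste0("%.17g", sep, "%.17g", sep, "%.17g"),
                     co[, 1], co[, 2], co[, 3]), path)
  mk <- markers(cloud)
  if (nrow(mk) > 0)
    utils::write.csv(mk, .sidecarPath(path), row.names = FALSE)
}

#' Read a point cloud
#'
#' Reads PLY (ASCII or binary-little-endian), PCD (ASCII) or plain
#' whitespace/CSV XYZ files. Only vertex coordinates are kept; colour and
#' normal attributes are ignored. Labelled markers are recovered from
#' comment-encoded lines (PLY/PCD) or a \code{<path>.markers.csv} sidecar
#' (XYZ/CSV).
#'
#' @param path input file path.
#' @param format one of "auto" (by extension), "ply", "pcd", "xyz", "csv".
#' @return A [PointCloud-class].
#' @export
readPointCloud <- function(path, format = c("auto", "ply", "pcd", "xyz",
                                            "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read point cloud: no such file ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", pcd = "pcd", csv = "csv", "xyz")
  }
  switch(format,
         ply = .readPLY(path),
         pcd = .readPCD(path),
         csv = .readXYZ(path, sep = ","),
         xyz = .readXYZ(path))
}

#' Write a point cloud
#'
#' @param cloud a [PointCloud-class].
#' @param path output file path (must be non-empty and in a writable
#'   directory).
#' @param format "ply" (ASCII), "ply_binary" (binary-little-endian), "pcd"
#'   (ASCII), "xyz" or "csv". For xyz/csv, markers go to a
#'   \code{<path>.markers.csv} sidecar.
#' @return invisibly, the path.
#' @export
writePointCloud <- function(cloud, path,
                            format = c("ply", "ply_binary", "pcd", "xyz",
                                       "csv")) {
  format <- match.arg(format)
  stopifnot(is(cloud, "PointCloud"))
  validObject(cloud)
  if (!is.character(path) || length(path) != 1 || !nzchar(path))
    stop("output path must be a non-empty string")
  if (!dir.exists(dirname(path)))
    stop("cannot write point cloud: no such directory ", dirname(path))
  switch(format,
         ply = .writePLY(cloud, path, binary = FALSE),
         ply_binary = .writePLY(cloud, path, binary = TRUE),
         pcd = .writePCD(cloud, path),
         xyz = .writeXYZ(cloud, path, sep = " "),
         csv = .writeXYZ(cloud, path, sep = ","))
  invisible(path)
}

#' Read / write a rigid transform as JSON
#'
#' The file is a JSON document with a 4x4 row-major homogeneous matrix under
#' \code{"matrix"} and a \code{"units"} field ("mm"). Reading validates the
#' rigid invariants: matrices whose rotation block is not orthonormal or has
#' determinant -1 (a reflection or shear, not a rigid motion) are rejected.
#'
#' @param path JSON file path.
#' @return \code{readTransform}: a [RigidTransform-class].
#' @export
readTransform <- function(path) {
  if (!file.exists(path)) stop("cannot read transform: no such file ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$matrix)) stop("transform JSON lacks a 'matrix' field: ", path)
  m <- as.matrix(doc$matrix)
  if (!all(dim(m) == c(4, 4)))
    stop("transform matrix must be 4x4 homogeneous: ", path)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("bottom row of the homogeneous matrix must be (0, 0, 0, 1): ", path)
  tf <- tryCatch(rigidTransform(m[1:3, 1:3], m[1:3, 4]),
                 error = function(e)
                   stop("not a rigid transform (", conditionMessage(e), "): ",
                        path, call. = FALSE))
  tf
}

#' @rdname readTransform
#' @param transform a [RigidTransform-class].
#' @return \code{writeTransform}: invisibly, the path.
#' @export
writeTransform <- function(transform, path) {
  stopifnot(is(transform, "RigidTransform"))
  validObject(transform)
  m <- asMatrix(transform)
  jsonlite::write_json(
    list(matrix = apply(m, 1, function(r) r, simplify = FALSE), units = "mm"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
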