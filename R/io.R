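#' Volume and projection I/O
#'
#' Volumes and projection stacks are stored as raw little-endian float64
#' (`.raw`) next to a JSON sidecar (`.json`) holding the shape and
#' geometry metadata; values are written in R array (column-major) order.
#' [writeVolumeTiff()] additionally exports per-slice 32-bit float TIFFs for
#' visual inspection.
#'
#' @param x a [Volume-class] / [ProjectionStack-class].
#' @param path base path; `.raw` and `.json` extensions are appended.
#' @return write functions return the base path invisibly; read functions
#'   return the reconstructed object.
#' @name volume-io
NULL

writeRawSidecar <- function(vals, meta, path) {
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(vals), con, size = 8, endian = "little")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

readRawValues <- function(path, n) {
  con <- file(paste0(path, ".raw"), "rb")
  on.exit(close(con))
  readBin(con, what = "numeric", n = n, size = 8, endian = "little")
}

#' @rdname volume-io
#' @export
writeVolume <- function(x, path) {
  stopifnot(is(x, "Volume"))
  writeRawSidecar(x@values,
                  list(type = "volume", dims = x@grid@dims,
                       spacing = x@grid@spacing, origin = x@grid@origin,
                       dtype = "float64-le"),
                  path)
}

#' @rdname volume-io
#' @export
readVolume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stopifnot(identical(meta$type, "volume"))
  g <- volumeGrid(meta$dims, meta$spacing, meta$origin)
  volume(array(readRawValues(path, prod(meta$dims)), dim = g@dims), g)
}

#' @rdname volume-io
#' @export
writeProjections <- function(x, path) {
  stopifnot(is(x, "ProjectionStack"))
  g <- x@geometry
  writeRawSidecar(x@values,
                  list(type = "projections",
                       dims = dim(x@values),
                       angles = g@angles,
                       sourceDetectorDistance = g@sourceDetectorDistance,
                       pitchX = g@pitchX, pitchY = g@pitchY,
                       detectorOrigin = g@detectorOrigin,
                       arcCenter = g@arcCenter,
                       dtype = "float64-le"),
                  path)
}

#' @rdname volume-io
#' @export
readProjections <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stopifnot(identical(meta$type, "projections"))
  g <- scanGeometry(meta$sourceDetectorDistance, meta$angles,
                    detectorRows = meta$dims[1], detectorCols = meta$dims[2],
                    pitchX = meta$pitchX, pitchY = meta$pitchY,
                    detectorOrigin = meta$detectorOrigin,
                    arcCenter = meta$arcCenter)
  projectionStack(array(readRawValues(path, prod(meta$dims)),
                        dim = meta$dims), g)
}

#' @rdname volume-io
#' @param normalize rescale slices to [0, 1] by the volume-wide min-max
#'   window (logged to the sidecar) as TIFF viewers expect; set FALSE to
#'   write raw float values.
#' @export
writeVolumeTiff <- function(x, path, normalize = TRUE) {
  stopifnot(is(x, "Volume"))
  v <- x@values
  lo <- min(v); hi <- max(v)
  if (normalize) v <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
  slices <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]))
  tiff::writeTIFF(slices, paste0(path, ".tif"), bits.per.sample = 32L)
  jsonlite::write_json(list(type = "tiff-window", min = lo, max = hi,
                            normalized = normalize),
                       paste0(path, ".window.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
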