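#' Construct a DBT scan geometry
#'
#' A C-arc tomosynthesis acquisition: the source rotates about `arcCenter`
#' within the YZ plane while the flat detector stays fixed in the plane
#' Z = 0. At the central 0 degree position the source sits
#' `sourceDetectorDistance` mm above `arcCenter`.
#'
#' @param sourceDetectorDistance source height (mm) above the detector plane
#'   at the central position.
#' @param angles angular positions (degrees), strictly increasing.
#' @param detectorRows,detectorCols detector pixel counts (rows along Y,
#'   columns along X).
#' @param pitchX,pitchY detector pixel pitch (mm).
#' @param detectorOrigin XY corner (mm) of detector pixel (1, 1); defaults to
#'   centering the detector on the origin.
#' @param arcCenter rotation center; defaults to the detector-plane point
#'   below the central source position, `c(0, 0, 0)`.
#' @return a [ScanGeometry-class] object.
#' @examples
#' g <- scanGeometry(100, c(-10, 0, 10), 64, 64, 0.5, 0.5)
#' sourcePosition(g, 2)
#' @export
scanGeometry <- function(sourceDetectorDistance, angles,
                         detectorRows, detectorCols,
                         pitchX, pitchY,
                         detectorOrigin = NULL, arcCenter = c(0, 0, 0)) {
  if (is.null(detectorOrigin)) {
    detectorOrigin <- c(-detectorCols * pitchX / 2,
                        -detectorRows * pitchY / 2)
  }
  new("ScanGeometry",
      sourceDetectorDistance = as.numeric(sourceDetectorDistance),
      angles = as.numeric(angles),
      detectorRows = as.integer(detectorRows),
      detectorCols = as.integer(detectorCols),
      pitchX = as.numeric(pitchX), pitchY = as.numeric(pitchY),
      detectorOrigin = as.numeric(detectorOrigin),
      arcCenter = as.numeric(arcCenter))
}

#' Construct a volume grid
#'
#' @param dims voxel counts (Nx, Ny, Nz).
#' @param spacing voxel pitch (dx, dy, dz) in mm.
#' @param origin position (mm) of the corner of voxel (1, 1, 1); defaults to
#'   centering the grid in XY with its bottom 1 mm above the detector.
#' @return a [VolumeGrid-class] object.
#' @export
volumeGrid <- function(dims, spacing, origin = NULL) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  if (is.null(origin)) {
    origin <- c(-dims[1] * spacing[1] / 2, -dims[2] * spacing[2] / 2, 1)
  }
  new("VolumeGrid", dims = dims, spacing = spacing,
      origin = as.numeric(origin))
}

#' Construct a Volume
#'
#' @param values numeric array of dim `gridDims(grid)` (a scalar is
#'   recycled), attenuation in 1/mm.
#' @param grid a [VolumeGrid-class].
#' @return a [Volume-class] object.
#' @export
volume <- function(values, grid) {
  if (length(values) == 1L)
    values <- array(as.numeric(values), dim = grid@dims)
  new("Volume", values = values, grid = grid)
}

#' Construct a ProjectionStack
#'
#' @param values numeric array (detectorRows, detectorCols, N_theta); a
#'   scalar is recycled.
#' @param geometry a [ScanGeometry-class].
#' @return a [ProjectionStack-class] object.
#' @export
projectionStack <- function(values, geometry) {
  d <- c(geometry@detectorRows, geometry@detectorCols,
         length(geometry@angles))
  if (length(values) == 1L) values <- array(as.numeric(values), dim = d)
  new("ProjectionStack", values = values, geometry = geometry)
}

#' The packaged Giotto-class acquisition preset
#'
#' Eleven equispaced views spanning -15 to +15 degrees from a source 690 mm
#' above the detector at the central position; a 3580 x 2812 pixel detector
#' (columns x rows) with 0.085 mm square pixels. Every field can be
#' overridden.
#'
#' @param ... overrides passed to [scanGeometry()].
#' @return a [ScanGeometry-class] object.
#' @examples
#' g <- giottoGeometry()
#' length(angles(g))
#' @export
giottoGeometry <- function(...) {
  defaults <- list(
    sourceDetectorDistance = 690,
    angles = seq(-15, 15, length.out = 11),
    detectorRows = 2812L, detectorCols = 3580L,
    pitchX = 0.085, pitchY = 0.085
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(scanGeometry, args)
}

#' Source position at one angular index
#'
#' Rotates the central source position (arcCenter + (0, 0, R), with R the
#' distance from the rotation center to the source) by the requested angle
#' about `arcCenter` within the YZ plane. The X coordinate equals the arc
#' center's X for every view.
#'
#' @param geometry a [ScanGeometry-class].
#' @param angleIndex 1-based index into `angles(geometry)`.
#' @return numeric length-3 point (mm).
#' @export
sourcePosition <- function(geometry, angleIndex) {
  n <- length(geometry@angles)
  if (!(is.numeric(angleIndex) && length(angleIndex) == 1L &&
        angleIndex == as.integer(angleIndex) &&
        angleIndex >= 1L && angleIndex <= n))
    stop("angleIndex out of range: need an integer in [1, ", n, "]")
  th <- geometry@angles[angleIndex] * pi / 180
  R <- geometry@sourceDetectorDistance - geometry@arcCenter[3]
  geometry@arcCenter + c(0, R * sin(th), R * cos(th))
}

#' Validate a geometry/grid pair
#'
#' Checks every class invariant plus the cross constraints: the volume must
#' lie strictly between the detector plane and every source position.
#' Returns the pair unchanged (invisibly, as a list) if all hold; otherwise
#' throws an error naming the offending field.
#'
#' @param geometry a [ScanGeometry-class].
#' @param grid a [VolumeGrid-class].
#' @return invisibly, `list(geometry = geometry, grid = grid)`.
#' @export
validateScan <- function(geometry, grid) {
  validObject(geometry)
  validObject(grid)
  zTop <- grid@origin[3] + grid@dims[3] * grid@spacing[3]
  zBottom <- grid@origin[3]
  if (zBottom <= 0)
    stop("origin: volume must lie strictly above the detector plane (Z > 0)")
  srcZ <- vapply(seq_along(geometry@angles),
                 function(i) sourcePosition(geometry, i)[3], numeric(1))
  if (any(srcZ <= zTop))
    stop("sourceDetectorDistance/angles: every source position must be ",
         "strictly above the top of the volume")
  invisible(list(geometry = geometry, grid = grid))
}

# Pack geometry + grid for the C++ core, for one angle (0-based internals).
packGeometry <- function(geometry, grid, angleIndex) {
  s <- sourcePosition(geometry, angleIndex)
  c(s,
    geometry@detectorOrigin[1], geometry@detectorOrigin[2],
    geometry@pitchX, geometry@pitchY,
    grid@origin, grid@spacing)
}

#' Read / write a scan geometry config file
#'
#' YAML with the [scanGeometry()] fields (lengths in mm, angles in degrees).
#' The string `"giotto"` for `preset` starts from [giottoGeometry()] and
#' applies any overriding fields present in the file.
#'
#' @param path file path.
#' @param geometry a [ScanGeometry-class] (for writing).
#' @return `readScanConfig()`: a [ScanGeometry-class];
#'   `writeScanConfig()`: the path, invisibly.
#' @export
readScanConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  preset <- cfg$preset
  cfg$preset <- NULL
  known <- c("sourceDetectorDistance", "angles", "detectorRows",
             "detectorCols", "pitchX", "pitchY", "detectorOrigin",
             "arcCenter")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown geometry fields: ", paste(bad, collapse = ", "))
  if (!is.null(preset)) {
    if (!identical(preset, "giotto")) stop("unknown preset: ", preset)
    do.call(giottoGeometry, cfg)
  } else {
    do.call(scanGeometry, cfg)
  }
}

#' @rdname readScanConfig
#' @export
writeScanConfig <- function(geometry, path) {
  yaml::write_yaml(list(
    sourceDetectorDistance = geometry@sourceDetectorDistance,
    angles = geometry@angles,
    detectorRows = geometry@detectorRows,
    detectorCols = geometry@detectorCols,
    pitchX = geometry@pitchX, pitchY = geometry@pitchY,
    detectorOrigin = geometry@detectorOrigin,
    arcCenter = geometry@arcCenter
  ), path)
  invisible(path)
}
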