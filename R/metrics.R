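#' Region of interest
#'
#' A rectangular in-plane region on one slice: 1-based inclusive index
#' ranges along X (rows of the slice array) and Y (columns).
#'
#' @param slice slice index (Z).
#' @param rows,cols integer ranges of voxel indices along X and Y.
#' @return classed list (`ROI`).
#' @export
roi <- function(slice, rows, cols) {
  stopifnot(length(rows) >= 1, length(cols) >= 1, slice >= 1)
  structure(list(slice = as.integer(slice), rows = as.integer(rows),
                 cols = as.integer(cols)), class = "ROI")
}

checkRoi <- function(x, r) {
  dm <- gridDims(x)
  if (r$slice > dm[3] || any(r$rows < 1) || any(r$rows > dm[1]) ||
      any(r$cols < 1) || any(r$cols > dm[2]))
    stop("ROI out of volume bounds")
}

#' ROI mean and standard deviation
#'
#' Arithmetic mean and population standard deviation (divisor n) of the
#' voxels inside the region -- the background uniformity / noise statistics
#' reported alongside reconstructions.
#'
#' @param x a [Volume-class].
#' @param r an [roi()].
#' @return named numeric: `mean`, `stddev`.
#' @export
roiStats <- function(x, r) {
  checkRoi(x, r)
  v <- x@values[r$rows, r$cols, r$slice]
  m <- mean(v)
  c(mean = m, stddev = sqrt(mean((v - m)^2)))
}

#' Axis-aligned line profile
#'
#' Voxel values along an axis-aligned segment on one slice, for overlay
#' plots across iterations. Start and end are 1-based (x, y) voxel indices;
#' exactly one coordinate may vary.
#'
#' @param x a [Volume-class].
#' @param slice slice index.
#' @param start,end length-2 integer voxel coordinates (x, y).
#' @return data.frame with `position` (voxel index along the varying axis)
#'   and `value`.
#' @export
lineProfile <- function(x, slice, start, end) {
  dm <- gridDims(x)
  stopifnot(length(start) == 2L, length(end) == 2L, slice >= 1,
            slice <= dm[3])
  if (all(start == end)) stop("start and end must differ")
  if (start[1] != end[1] && start[2] != end[2])
    stop("profile must be axis-aligned")
  if (any(c(start, end) < 1) || any(start > dm[1:2]) || any(end > dm[1:2]))
    stop("profile out of volume bounds")
  if (start[1] != end[1]) {
    idx <- start[1]:end[1]
    val <- x@values[idx, start[2], slice]
  } else {
    idx <- start[2]:end[2]
    val <- x@values[start[1], idx, slice]
  }
  data.frame(position = idx, value = val)
}

#' Object/background contrast
#'
#' `(mean(object) - mean(background)) / mean(background)` -- an explicit
#' operationalization of the qualitative contrast enhancement observed
#' across iterations.
#'
#' @param x a [Volume-class].
#' @param objectRoi,backgroundRoi [roi()] regions.
#' @return scalar.
#' @export
contrast <- function(x, objectRoi, backgroundRoi) {
  mo <- roiStats(x, objectRoi)[["mean"]]
  mb <- roiStats(x, backgroundRoi)[["mean"]]
  if (mb == 0) stop("background mean is zero; contrast undefined")
  (mo - mb) / mb
}

#' Relative recovery error
#'
#' `||x - truth|| / ||truth||` over the whole volume.
#'
#' @param x,truth [Volume-class] objects on the same grid.
#' @return scalar.
#' @export
recoveryError <- function(x, truth) {
  if (!identical(gridDims(x), gridDims(truth)))
    stop("x and truth must share a grid")
  nt <- sqrt(sum(truth@values^2))
  if (nt == 0) stop("truth is identically zero; relative error undefined")
  sqrt(sum((x@values - truth@values)^2)) / nt
}
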