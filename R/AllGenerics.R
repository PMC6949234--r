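#' @name accessors
#' @title Accessors for tomosgp data objects
#'
#' @description Slot accessors for the core data classes. `values()` returns
#' the numeric array of a [Volume-class] or [ProjectionStack-class];
#' `grid()` the [VolumeGrid-class] of a volume; `geometry()` the
#' [ScanGeometry-class] of a projection stack; `angles()` the angular
#' positions (degrees); `gridDims()`, `gridSpacing()` and `gridOrigin()` the
#' lattice counts, pitches and corner of a grid or volume.
#'
#' @param x a tomosgp object.
#' @return the corresponding slot value.
#' @examples
#' g <- giottoGeometry()
#' angles(g)
#' vg <- volumeGrid(c(4, 4, 2), c(1, 1, 1), c(0, 0, 10))
#' gridDims(vg)
NULL

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("grid", function(x) standardGeneric("grid"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname accessors
setMethod("values", "Volume", function(x) x@values)

#' @rdname accessors
setMethod("values", "ProjectionStack", function(x) x@values)

#' @rdname accessors
setMethod("grid", "Volume", function(x) x@grid)

#' @rdname accessors
setMethod("geometry", "ProjectionStack", function(x) x@geometry)

#' @rdname accessors
setMethod("angles", "ScanGeometry", function(x) x@angles)

#' @rdname accessors
setMethod("angles", "ProjectionStack", function(x) x@geometry@angles)

#' @rdname accessors
setMethod("gridDims", "VolumeGrid", function(x) x@dims)

#' @rdname accessors
setMethod("gridDims", "Volume", function(x) x@grid@dims)

#' @rdname accessors
setMethod("gridSpacing", "VolumeGrid", function(x) x@spacing)

#' @rdname accessors
setMethod("gridSpacing", "Volume", function(x) x@grid@spacing)

#' @rdname accessors
setMethod("gridOrigin", "VolumeGrid", function(x) x@origin)

#' @rdname accessors
setMethod("gridOrigin", "Volume", function(x) x@grid@origin)

setMethod("show", "ScanGeometry", function(object) {
  cat("ScanGeometry:", length(object@angles), "angles in [",
      min(object@angles), ",", max(object@angles), "] deg;",
      "source height", object@sourceDetectorDistance, "mm\n")
  cat("  detector:", object@detectorRows, "x", object@detectorCols,
      "pixels at", object@pitchY, "x", object@pitchX, "mm\n")
})

setMethod("show", "VolumeGrid", function(object) {
  cat("VolumeGrid:", paste(object@dims, collapse = " x "), "voxels at",
      paste(object@spacing, collapse = " x "), "mm; origin (",
      paste(object@origin, collapse = ", "), ") mm\n")
})

setMethod("show", "Volume", function(object) {
  cat("Volume:", paste(object@grid@dims, collapse = " x "),
      "voxels; range [", signif(min(object@values), 4), ",",
      signif(max(object@values), 4), "] 1/mm\n")
})

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@values)
  cat("ProjectionStack:", d[3], "views of", d[1], "x", d[2],
      "pixels; range [", signif(min(object@values), 4), ",",
      signif(max(object@values), 4), "]\n")
})
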