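#' @useDynLib tomosgp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject setClass setGeneric setMethod is slot
#' @importFrom stats rnorm sd
#' @importFrom utils write.csv read.csv head tail
NULL

#' ScanGeometry: DBT acquisition geometry
#'
#' Describes a C-arc digital breast tomosynthesis acquisition: a point X-ray
#' source moving on an arc in the YZ plane above a stationary flat detector
#' occupying the plane Z = 0. X runs along detector columns, Y along the
#' source-motion direction, Z up toward the source. All lengths are in mm,
#' angles in degrees.
#'
#' @slot sourceDetectorDistance height (mm) of the source above the detector
#'   plane at the central (0 degree) position.
#' @slot angles ordered vector of angular positions (degrees) on the arc.
#' @slot detectorRows,detectorCols detector pixel counts (rows = Y, cols = X).
#' @slot pitchX,pitchY detector pixel pitch (mm) along columns / rows.
#' @slot detectorOrigin XY position (mm) of the corner of pixel (1, 1).
#' @slot arcCenter 3D point about which the source rotates; defaults to a
#'   point on the detector plane directly below the central source position.
#'
#' @exportClass ScanGeometry
setClass("ScanGeometry",
  representation(
    sourceDetectorDistance = "numeric",
    angles = "numeric",
    detectorRows = "integer",
    detectorCols = "integer",
    pitchX = "numeric",
    pitchY = "numeric",
    detectorOrigin = "numeric",
    arcCenter = "numeric"
  )
)

setValidity("ScanGeometry", function(object) {
  msg <- character(0)
  if (length(object@angles) < 1L)
    msg <- c(msg, "angles: at least one angular position is required")
  if (any(diff(object@angles) <= 0))
    msg <- c(msg, "angles: must be strictly increasing")
  if (object@sourceDetectorDistance <= 0)
    msg <- c(msg, "sourceDetectorDistance: must be > 0")
  if (object@pitchX <= 0) msg <- c(msg, "pitchX: must be > 0")
  if (object@pitchY <= 0) msg <- c(msg, "pitchY: must be > 0")
  if (object@detectorRows < 1L) msg <- c(msg, "detectorRows: must be >= 1")
  if (object@detectorCols < 1L) msg <- c(msg, "detectorCols: must be >= 1")
  if (length(object@detectorOrigin) != 2L)
    msg <- c(msg, "detectorOrigin: must have length 2")
  if (length(object@arcCenter) != 3L)
    msg <- c(msg, "arcCenter: must have length 3")
  if (!all(is.finite(object@angles)))
    msg <- c(msg, "angles: must be finite")
  if (length(msg)) msg else TRUE
})

#' VolumeGrid: the voxel lattice of the reconstructed volume
#'
#' @slot dims integer counts (Nx, Ny, Nz).
#' @slot spacing voxel pitch (dx, dy, dz) in mm; dz is the slice thickness.
#' @slot origin 3D position (mm) of the corner of voxel (1, 1, 1) in the
#'   detector frame. Voxels are half-open boxes [corner, corner + pitch).
#'
#' @exportClass VolumeGrid
setClass("VolumeGrid",
  representation(dims = "integer", spacing = "numeric", origin = "numeric")
)

setValidity("VolumeGrid", function(object) {
  msg <- character(0)
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims: three counts, all >= 1")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing: three pitches, all > 0")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin: three finite coordinates")
  if (length(msg)) msg else TRUE
})

#' Volume: voxelized attenuation map
#'
#' @slot values numeric array of dim (Nx, Ny, Nz), attenuation in 1/mm.
#' @slot grid the [VolumeGrid-class] the values live on.
#' @exportClass Volume
setClass("Volume", representation(values = "array", grid = "VolumeGrid"))

setValidity("Volume", function(object) {
  msg <- character(0)
  if (!identical(dim(object@values), as.integer(object@grid@dims)))
    msg <- c(msg, "values: dim must equal grid dims")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values: must be finite")
  if (length(msg)) msg else TRUE
})

#' ProjectionStack: the tomographic data vector b
#'
#' @slot values numeric array of dim (detectorRows, detectorCols, N_theta):
#'   one detector image per angular position, in line-integral units
#'   (mm times attenuation).
#' @slot geometry the [ScanGeometry-class] the stack was acquired under.
#' @exportClass ProjectionStack
setClass("ProjectionStack",
  representation(values = "array", geometry = "ScanGeometry")
)

setValidity("ProjectionStack", function(object) {
  g <- object@geometry
  expected <- c(g@detectorRows, g@detectorCols, length(g@angles))
  msg <- character(0)
  if (!identical(dim(object@values), as.integer(expected)))
    msg <- c(msg, "values: dim must be (detectorRows, detectorCols, N_theta)")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values: must be finite")
  if (length(msg)) msg else TRUE
})

#' ObjectiveConfig: regularization settings of the reconstruction model
#'
#' The reconstruction objective is f(x) = 1/2 ||Ax - b||^2 + lambda * TV(x),
#' with TV smoothed by a constant beta so it is differentiable everywhere.
#'
#' @slot lambda regularization weight (> 0).
#' @slot beta TV smoothing constant (> 0), in voxel-value units (1/mm).
#' @slot anisotropy weight applied to the Z forward difference inside the
#'   voxelwise gradient magnitude (1 treats the three directions equally).
#' @exportClass ObjectiveConfig
setClass("ObjectiveConfig",
  representation(lambda = "numeric", beta = "numeric", anisotropy = "numeric")
)

setValidity("ObjectiveConfig", function(object) {
  msg <- character(0)
  if (object@lambda < 0) msg <- c(msg, "lambda: must be >= 0")
  if (object@beta <= 0) msg <- c(msg, "beta: must be > 0")
  if (object@anisotropy <= 0) msg <- c(msg, "anisotropy: must be > 0")
  if (length(msg)) msg else TRUE
})

#' SolverConfig: SGP algorithm settings
#'
#' @slot sigma Armijo sufficient-decrease parameter, in (0, 1).
#' @slot gamma backtracking shrink factor, in (0, 1).
#' @slot alphaMin,alphaMax steplength bounds (0 < alphaMin <= alphaMax).
#' @slot alpha0 initial steplength, inside the bounds.
#' @slot maxiter iteration cap.
#' @slot tol relative objective-change tolerance of the stopping rule.
#' @slot bbMemory number of recent BB2 steplengths kept for the alternation.
#' @slot bbTau initial switching threshold of the BB alternation.
#' @slot seed integer seed for any randomized initialization.
#' @exportClass SolverConfig
setClass("SolverConfig",
  representation(
    sigma = "numeric", gamma = "numeric",
    alphaMin = "numeric", alphaMax = "numeric", alpha0 = "numeric",
    maxiter = "integer", tol = "numeric",
    bbMemory = "integer", bbTau = "numeric", seed = "integer"
  )
)

setValidity("SolverConfig", function(object) {
  msg <- character(0)
  if (object@sigma <= 0 || object@sigma >= 1)
    msg <- c(msg, "sigma: must be in (0, 1)")
  if (object@gamma <= 0 || object@gamma >= 1)
    msg <- c(msg, "gamma: must be in (0, 1)")
  if (!(object@alphaMin > 0 && object@alphaMin <= object@alphaMax))
    msg <- c(msg, "alphaMin: need 0 < alphaMin <= alphaMax")
  if (object@alpha0 < object@alphaMin || object@alpha0 > object@alphaMax)
    msg <- c(msg, "alpha0: must lie in [alphaMin, alphaMax]")
  if (object@maxiter < 1L) msg <- c(msg, "maxiter: must be >= 1")
  if (object@tol <= 0) msg <- c(msg, "tol: must be > 0")
  if (object@bbMemory < 1L) msg <- c(msg, "bbMemory: must be >= 1")
  if (object@bbTau <= 0 || object@bbTau >= 1)
    msg <- c(msg, "bbTau: must be in (0, 1)")
  if (length(msg)) msg else TRUE
})
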