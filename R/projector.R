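#' One distance-driven row of the system matrix
#'
#' Computes the sparse row of A for one detector pixel at one angle: for each
#' volume slice the pixel's X/Y boundaries are centrally projected from the
#' source onto the slice mid-plane, and every voxel overlapping that
#' footprint receives weight
#' `(overlap_x * overlap_y) / (footprint_x * footprint_y) * dz / cos(phi)`,
#' phi being the angle between the central pixel ray and the Z axis. Weights
#' are effective intersection path lengths in mm, so the dot product of a row
#' with an attenuation volume is a Beer-Lambert line integral.
#'
#' @param geometry a [ScanGeometry-class].
#' @param grid a [VolumeGrid-class].
#' @param angleIndex,pixelRow,pixelCol 1-based indices of the view and
#'   detector pixel.
#' @return a list with `indices` (1-based flat voxel indices into the
#'   volume array) and `weights` (nonnegative path lengths, mm). Rays that
#'   miss the volume give an empty row.
#' @seealso [oracleRow()] for the brute-force ray-sampling reference.
#' @export
ddRow <- function(geometry, grid, angleIndex, pixelRow, pixelCol) {
  stopifnot(pixelRow >= 1, pixelRow <= geometry@detectorRows,
            pixelCol >= 1, pixelCol <= geometry@detectorCols)
  validateScan(geometry, grid)
  res <- cpp_dd_row(packGeometry(geometry, grid, angleIndex), grid@dims,
                    as.integer(pixelRow) - 1L, as.integer(pixelCol) - 1L,
                    0L, grid@dims[3])
  list(indices = as.integer(res$indices) + 1L, weights = res$weights)
}

#' Brute-force ray-sampling reference row
#'
#' Independent reference for [ddRow()]: casts `subsamples^2` rays through a
#' stratified grid of points over the pixel area, computes the exact
#' ray-voxel intersection length of each ray with each voxel by slab
#' clipping, and averages over rays. Converges to the exact beam/voxel
#' effective path length as `subsamples` grows.
#'
#' @inheritParams ddRow
#' @param subsamples number of sub-rays per pixel axis (>= 1).
#' @return a list with 1-based `indices` and averaged `weights` (mm).
#' @export
oracleRow <- function(geometry, grid, angleIndex, pixelRow, pixelCol,
                      subsamples = 32L) {
  stopifnot(subsamples >= 1L)
  s <- sourcePosition(geometry, angleIndex)
  px <- geometry@pitchX; py <- geometry@pitchY
  xlo <- geometry@detectorOrigin[1] + (pixelCol - 1) * px
  ylo <- geometry@detectorOrigin[2] + (pixelRow - 1) * py
  off <- (seq_len(subsamples) - 0.5) / subsamples
  pts <- expand.grid(x = xlo + off * px, y = ylo + off * py)
  nray <- nrow(pts)
  dirx <- pts$x - s[1]; diry <- pts$y - s[2]; dirz <- -s[3]
  rayLen <- sqrt(dirx^2 + diry^2 + dirz^2)

  dm <- grid@dims; sp <- grid@spacing; or <- grid@origin
  # bounding voxel ranges from the footprints at the volume's Z extremes
  zr <- c(or[3], or[3] + dm[3] * sp[3])
  tEnds <- range((s[3] - zr) / s[3])
  xproj <- range(s[1] + outer(c(xlo, xlo + px) - s[1], tEnds))
  yproj <- range(s[2] + outer(c(ylo, ylo + py) - s[2], tEnds))
  i0 <- max(1L, floor((xproj[1] - or[1]) / sp[1]) + 1L)
  i1 <- min(dm[1], floor((xproj[2] - or[1]) / sp[1]) + 1L)
  j0 <- max(1L, floor((yproj[1] - or[2]) / sp[2]) + 1L)
  j1 <- min(dm[2], floor((yproj[2] - or[2]) / sp[2]) + 1L)

  idx <- integer(0); w <- numeric(0)
  if (i0 <= i1 && j0 <= j1) {
    for (k in seq_len(dm[3])) {
      z0 <- or[3] + (k - 1) * sp[3]; z1 <- z0 + sp[3]
      ta <- (z0 - s[3]) / dirz; tb <- (z1 - s[3]) / dirz
      tz0 <- pmin(ta, tb); tz1 <- pmax(ta, tb)
      for (j in j0:j1) {
        y0 <- or[2] + (j - 1) * sp[2]; y1 <- y0 + sp[2]
        ta <- (y0 - s[2]) / diry; tb <- (y1 - s[2]) / diry
        ty0 <- pmin(ta, tb); ty1 <- pmax(ta, tb)
        for (i in i0:i1) {
          x0 <- or[1] + (i - 1) * sp[1]; x1 <- x0 + sp[1]
          ta <- (x0 - s[1]) / dirx; tb <- (x1 - s[1]) / dirx
          tx0 <- pmin(ta, tb); tx1 <- pmax(ta, tb)
          tin <- pmax(tx0, ty0, tz0, 0)
          tout <- pmin(tx1, ty1, tz1, 1)
          len <- pmax(tout - tin, 0) * rayLen
          wij <- sum(len) / nray
          if (wij > 0) {
            idx <- c(idx, i + dm[1] * ((j - 1) + dm[2] * (k - 1)))
            w <- c(w, wij)
          }
        }
      }
    }
  }
  list(indices = idx, weights = w)
}

#' Forward projection (A x)
#'
#' Matrix-free distance-driven forward projection of a volume onto the
#' detector for every view: rows of the system matrix are recomputed on the
#' fly and never stored. With `chunkSlices < Nz` the volume is processed in
#' Z-chunks whose partial projections are accumulated; by linearity the
#' result agrees with the unchunked evaluation to roundoff.
#'
#' @param x a [Volume-class].
#' @param geometry a [ScanGeometry-class].
#' @param grid the volume's [VolumeGrid-class]; defaults to `grid(x)`.
#' @param chunkSlices slices per chunk (defaults to all of them).
#' @return a [ProjectionStack-class].
#' @export
forwardProject <- function(x, geometry, grid = NULL, chunkSlices = NULL) {
  if (is.null(grid)) grid <- x@grid
  if (!identical(dim(x@values), as.integer(grid@dims)))
    stop("volume/grid shape mismatch")
  validateScan(geometry, grid)
  Nz <- grid@dims[3]
  if (is.null(chunkSlices)) chunkSlices <- Nz
  stopifnot(chunkSlices >= 1L, chunkSlices <= Nz)
  nt <- length(geometry@angles)
  out <- array(0, dim = c(geometry@detectorRows, geometry@detectorCols, nt))
  for (k0 in seq(0L, Nz - 1L, by = chunkSlices)) {
    k1 <- min(k0 + chunkSlices, Nz)
    for (a in seq_len(nt)) {
      out[, , a] <- out[, , a] +
        cpp_forward_angle(as.numeric(x@values),
                          packGeometry(geometry, grid, a), grid@dims,
                          geometry@detectorRows, geometry@detectorCols,
                          as.integer(k0), as.integer(k1))
    }
  }
  projectionStack(out, geometry)
}

#' Backward projection (A^T r)
#'
#' Exact adjoint of [forwardProject()]: the same distance-driven weights are
#' accumulated into voxels. Chunks along Z write disjoint slice blocks, so
#' the result is independent of `chunkSlices`.
#'
#' @param r a [ProjectionStack-class].
#' @param geometry the scan geometry; defaults to `geometry(r)`.
#' @param grid a [VolumeGrid-class].
#' @param chunkSlices slices per chunk (defaults to all of them).
#' @return a [Volume-class].
#' @export
backProject <- function(r, grid, geometry = NULL, chunkSlices = NULL) {
  if (is.null(geometry)) geometry <- r@geometry
  d <- dim(r@values)
  if (!identical(d, as.integer(c(geometry@detectorRows,
                                 geometry@detectorCols,
                                 length(geometry@angles)))))
    stop("projection/geometry shape mismatch")
  validateScan(geometry, grid)
  Nz <- grid@dims[3]
  if (is.null(chunkSlices)) chunkSlices <- Nz
  stopifnot(chunkSlices >= 1L, chunkSlices <= Nz)
  acc <- numeric(prod(grid@dims))
  for (k0 in seq(0L, Nz - 1L, by = chunkSlices)) {
    k1 <- min(k0 + chunkSlices, Nz)
    for (a in seq_along(geometry@angles)) {
      acc <- acc + cpp_back_angle(r@values[, , a, drop = TRUE],
                                  packGeometry(geometry, grid, a),
                                  grid@dims, as.integer(k0), as.integer(k1))
    }
  }
  volume(array(acc, dim = grid@dims), grid)
}

#' Apply a projection operator in Z-chunks
#'
#' Convenience wrapper over [forwardProject()] / [backProject()] exposing the
#' chunked-evaluation contract: the output equals the unchunked result for
#' any chunk size.
#'
#' @param operator `"forward"` or `"backward"`.
#' @param input a [Volume-class] (forward) or [ProjectionStack-class]
#'   (backward).
#' @param geometry a [ScanGeometry-class].
#' @param grid a [VolumeGrid-class].
#' @param chunkSlices slices per chunk, in `[1, Nz]`.
#' @return a [ProjectionStack-class] or [Volume-class].
#' @export
chunkedApply <- function(operator = c("forward", "backward"), input,
                         geometry, grid, chunkSlices) {
  operator <- match.arg(operator)
  if (operator == "forward")
    forwardProject(input, geometry, grid, chunkSlices = chunkSlices)
  else
    backProject(input, grid, geometry, chunkSlices = chunkSlices)
}

#' Density of the system matrix
#'
#' Fraction of nonzero entries of A, counted row by row with the
#' distance-driven weights: `sum(nnz) / (N_d * N_v)`. Intended for
#' small-to-moderate geometries; rows are generated on the fly.
#'
#' @param geometry a [ScanGeometry-class].
#' @param grid a [VolumeGrid-class].
#' @return a scalar in (0, 1].
#' @export
matrixDensity <- function(geometry, grid) {
  validateScan(geometry, grid)
  nnz <- 0
  for (a in seq_along(geometry@angles)) {
    nnz <- nnz + cpp_nnz_angle(packGeometry(geometry, grid, a), grid@dims,
                               geometry@detectorRows, geometry@detectorCols)
  }
  Nd <- as.numeric(geometry@detectorRows) * geometry@detectorCols *
    length(geometry@angles)
  Nv <- prod(as.numeric(grid@dims))
  nnz / (Nd * Nv)
}
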