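# Shared fixtures: tiny geometries, random problems, and independent oracles.

# small C-arc scan over a centered detector
smallScan <- function(nRow = 6L, nCol = 6L, angles = c(-15, 0, 15),
                      pitch = 1, h = 200) {
  scanGeometry(h, angles, nRow, nCol, pitch, pitch)
}

# grid centered under the detector, bottom at z0
smallGrid <- function(dims = c(8, 8, 4), sp = c(1, 1, 1), z0 = 0.5) {
  volumeGrid(dims, sp, c(-dims[1] * sp[1] / 2, -dims[2] * sp[2] / 2, z0))
}

# a geometry in which A is (numerically) a permutation matrix pairing voxel
# (ix, jy) with detector pixel (row = jy, col = ix): one slice of unit
# thickness, detector grid congruent to the voxel grid, source so high that
# all rays are vertical to ~1e-12
identityScan <- function(n = 8L) {
  list(geometry = scanGeometry(1e12, 0, n, n, 1, 1,
                               detectorOrigin = c(-n / 2, -n / 2)),
       grid = volumeGrid(c(n, n, 1), c(1, 1, 1), c(-n / 2, -n / 2, 1e-9)))
}

randomVolume <- function(grid, seed) {
  set.seed(seed)
  volume(array(runif(prod(gridDims(grid))), dim = gridDims(grid)), grid)
}

randomStack <- function(geometry, seed) {
  set.seed(seed)
  d <- c(geometry@detectorRows, geometry@detectorCols,
         length(angles(geometry)))
  projectionStack(array(rnorm(prod(d)), dim = d), geometry)
}

# random valid (geometry, grid) pair within the stated size bounds
randomScanPair <- function(seed, maxDims = c(16, 16, 8), maxAngles = 3L) {
  set.seed(seed)
  dims <- pmax(2L, sapply(maxDims, function(m) sample.int(m, 1)))
  sp <- runif(3, 0.4, 1.5)
  z0 <- runif(1, 0.3, 2)
  nA <- sample.int(maxAngles, 1)
  ang <- sort(runif(nA, -20, 20))
  while (any(diff(ang) <= 1e-6)) ang <- sort(runif(nA, -20, 20))
  h <- runif(1, 30, 800)
  nRow <- sample(4:10, 1); nCol <- sample(4:10, 1)
  pitch <- runif(2, 0.3, 1.5)
  g <- scanGeometry(h, ang, nRow, nCol, pitch[1], pitch[2])
  vg <- volumeGrid(dims, sp,
                   c(-dims[1] * sp[1] / 2, -dims[2] * sp[2] / 2, z0))
  list(geometry = g, grid = vg)
}

# independent triple-loop evaluation of the smoothed TV (replicate boundary)
naiveTV <- function(v, beta) {
  d <- dim(v)
  tot <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    du <- if (i < d[1]) v[i + 1, j, k] - v[i, j, k] else 0
    dv <- if (j < d[2]) v[i, j + 1, k] - v[i, j, k] else 0
    dw <- if (k < d[3]) v[i, j, k + 1] - v[i, j, k] else 0
    tot <- tot + sqrt(du^2 + dv^2 + dw^2 + beta^2)
  }
  tot
}

# system matrix assembled explicitly from ddRow, as a triplet list
assembleMatrix <- function(geometry, grid) {
  rows <- list()
  n <- 0L
  for (a in seq_along(angles(geometry)))
    for (cl in seq_len(geometry@detectorCols))
      for (r in seq_len(geometry@detectorRows)) {
        n <- n + 1L
        rows[[n]] <- ddRow(geometry, grid, a, r, cl)
      }
  rows
}

# flat index of detector pixel (r, c, a) matching the array layout
flatPixelIndex <- function(geometry, r, cl, a) {
  nR <- geometry@detectorRows; nC <- geometry@detectorCols
  r + nR * ((cl - 1L) + nC * (a - 1L))
}

# plain projected gradient descent with a tiny fixed step 1/L; the
# slow-but-sure reference solver for the SGP cross-check
referencePG <- function(b, grid, objConfig, iters, x0) {
  g <- b@geometry
  # Lipschitz bound: ||A||^2 via power iteration plus the TV Hessian bound
  v <- array(1, dim = gridDims(grid))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in 1:40) {
    w <- values(backProject(forwardProject(volume(v, grid), g, grid),
                            grid, g))
    lam <- sum(w * v)
    v <- w / sqrt(sum(w^2))
  }
  L <- 1.05 * lam + objConfig@lambda * 12 / objConfig@beta
  tau <- 1 / L
  x <- x0
  for (i in seq_len(iters)) {
    ev <- objectiveGradient(volume(x, grid), b, objConfig)
    x <- pmax(x - tau * ev$gradient, 0)
  }
  list(x = x, f = objectiveGradient(volume(x, grid), b, objConfig)$f)
}
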