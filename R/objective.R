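#' Objective configuration
#'
#' Settings of the reconstruction model
#' `f(x) = 1/2 ||Ax - b||^2 + lambda * sum_j sqrt(||grad x_j||^2 + beta^2)`.
#' The voxelwise gradient uses forward differences along the three Cartesian
#' directions with replicate (Neumann) boundaries, so constant volumes are
#' TV-stationary. `beta` smooths the TV seminorm at zero gradient;
#' `lambda` has no universal default and must be chosen per acquisition
#' (see [tuneLambda()]).
#'
#' @param lambda regularization weight (>= 0; zero disables the prior,
#'   reducing the model to nonnegative least squares).
#' @param beta smoothing constant (> 0); default 1e-3 in reconstruction
#'   units.
#' @param anisotropy weight on the Z forward difference inside the gradient
#'   magnitude; 1 (default) treats all directions equally.
#' @return an [ObjectiveConfig-class].
#' @export
objectiveConfig <- function(lambda, beta = 1e-3, anisotropy = 1) {
  new("ObjectiveConfig", lambda = as.numeric(lambda),
      beta = as.numeric(beta), anisotropy = as.numeric(anisotropy))
}

# forward difference along dimension d with replicate (Neumann) boundary:
# the difference at the last plane is identically zero
fwdDiff <- function(a, d) {
  n <- dim(a)[d]
  if (n == 1L) return(array(0, dim = dim(a)))
  idx <- c(seq_len(n)[-1L], n)
  out <- switch(d,
                a[idx, , , drop = FALSE],
                a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE]) - a
  out
}

# shift an array forward along dimension d, zero-filling the first plane
# (adjoint of the forward difference's neighbor term)
shiftFwd <- function(a, d) {
  n <- dim(a)[d]
  out <- array(0, dim = dim(a))
  if (n == 1L) return(out)
  s1 <- seq_len(n - 1L)
  s2 <- s1 + 1L
  switch(d,
         out[s2, , ] <- a[s1, , , drop = FALSE],
         out[, s2, ] <- a[, s1, , drop = FALSE],
         out[, , s2] <- a[, , s1, drop = FALSE])
  out
}

asVolumeValues <- function(x) if (is(x, "Volume")) x@values else x

#' Least-squares data fidelity
#'
#' `1/2 ||Ax - b||^2` with A the distance-driven projector.
#'
#' @param x a [Volume-class].
#' @param b a [ProjectionStack-class].
#' @param geometry,grid scan geometry and grid (default from the objects).
#' @param Ax optional precomputed `forwardProject(x, ...)` to reuse.
#' @return scalar.
#' @export
leastSquares <- function(x, b, geometry = NULL, grid = NULL, Ax = NULL) {
  if (is.null(geometry)) geometry <- b@geometry
  if (is.null(grid)) grid <- x@grid
  if (is.null(Ax)) Ax <- forwardProject(x, geometry, grid)
  0.5 * sum((Ax@values - b@values)^2)
}

#' Smoothed total variation
#'
#' `sum_j sqrt(u_j^2 + v_j^2 + (a w_j)^2 + beta^2)` where (u, v, w) are the
#' forward differences of the volume along X, Y, Z with replicate boundary
#' and `a` the Z anisotropy weight. For a constant volume the value is
#' `N_v * beta`.
#'
#' @param x a [Volume-class] or numeric 3D array.
#' @param beta smoothing constant (> 0).
#' @param anisotropy Z-difference weight (default 1).
#' @return scalar.
#' @export
tvValue <- function(x, beta, anisotropy = 1) {
  stopifnot(beta > 0)
  v <- asVolumeValues(x)
  u <- fwdDiff(v, 1L); vy <- fwdDiff(v, 2L); w <- fwdDiff(v, 3L)
  sum(sqrt(u^2 + vy^2 + (anisotropy * w)^2 + beta^2))
}

#' Analytic gradient of the smoothed TV
#'
#' Each voxel receives the derivative of its own smoothed-magnitude term
#' plus the adjoint contributions of its three backward neighbors' terms.
#' For Neumann boundaries the gradient of a constant volume is zero and the
#' gradient always sums to zero over the volume.
#'
#' @inheritParams tvValue
#' @return array of the same shape as `x`.
#' @export
tvGradient <- function(x, beta, anisotropy = 1) {
  stopifnot(beta > 0)
  v <- asVolumeValues(x)
  u <- fwdDiff(v, 1L); vy <- fwdDiff(v, 2L); w <- fwdDiff(v, 3L)
  g <- sqrt(u^2 + vy^2 + (anisotropy * w)^2 + beta^2)
  P <- u / g; Q <- vy / g; W <- anisotropy^2 * w / g
  -(P + Q + W) + shiftFwd(P, 1L) + shiftFwd(Q, 2L) + shiftFwd(W, 3L)
}

# Positive part of the TV gradient splitting grad TV = V - U used by the
# SGP scaling matrix. Writing each voxel's gradient as
#   (x_j - x_{j+e})/g_j  (own term, per direction, absent at the far plane)
# + (x_j - x_{j-e})/g_{j-e}  (adjoint term, absent at the near plane),
# the terms carrying +x_j collect into V = x * c with
#   c = sum_e [ 1/g_j  (where the own term exists)
#             + 1/g_{j-e} (where the adjoint term exists) ],
# so V >= 0 whenever x >= 0. U = V - grad TV collects the neighbor values.
tvSplitPositive <- function(x, beta, anisotropy = 1) {
  v <- asVolumeValues(x)
  u <- fwdDiff(v, 1L); vy <- fwdDiff(v, 2L); w <- fwdDiff(v, 3L)
  g <- sqrt(u^2 + vy^2 + (anisotropy * w)^2 + beta^2)
  dm <- dim(v)
  inv <- 1 / g
  coef <- array(0, dim = dm)
  for (d in 1:3) {
    own <- inv
    n <- dm[d]
    fac <- if (d == 3L) anisotropy^2 else 1
    if (n > 1L) {
      # own term exists where the forward difference is a real term
      switch(d,
             own[n, , ] <- 0,
             own[, n, ] <- 0,
             own[, , n] <- 0)
      coef <- coef + fac * (own + shiftFwd(inv, d))
    }
  }
  v * coef
}

#' Objective value and gradient
#'
#' Evaluates `f(x) = 1/2 ||Ax - b||^2 + lambda TV(x)` and its gradient
#' `A^T(Ax - b) + lambda grad TV(x)` with one forward and one backward
#' projection. The forward projection `Ax` is returned so callers (the
#' backtracking line search in particular) can re-evaluate trial objectives
#' without further projections.
#'
#' @param x a [Volume-class].
#' @param b a [ProjectionStack-class].
#' @param config an [ObjectiveConfig-class].
#' @param geometry,grid defaults from the objects.
#' @param Ax optional cached forward projection of `x`.
#' @param chunkSlices optional Z-chunk size used for the projections and the
#'   TV terms (halo slices make the chunked evaluation exact).
#' @return list with `f`, `gradient` (array), `ls`, `tv`, `Ax`
#'   (ProjectionStack) and `gradLS` (array, the data-term gradient).
#' @export
objectiveGradient <- function(x, b, config, geometry = NULL, grid = NULL,
                              Ax = NULL, chunkSlices = NULL) {
  if (is.null(geometry)) geometry <- b@geometry
  if (is.null(grid)) grid <- x@grid
  if (is.null(Ax)) Ax <- forwardProject(x, geometry, grid,
                                        chunkSlices = chunkSlices)
  resid <- Ax@values - b@values
  ls <- 0.5 * sum(resid^2)
  tv <- if (is.null(chunkSlices))
    tvValue(x, config@beta, config@anisotropy)
  else tvChunked(x, config@beta, chunkSlices, config@anisotropy)
  gradLS <- backProject(projectionStack(resid, geometry), grid,
                        chunkSlices = chunkSlices)@values
  gtv <- if (is.null(chunkSlices))
    tvGradient(x, config@beta, config@anisotropy)
  else tvGradientChunked(x, config@beta, chunkSlices, config@anisotropy)
  list(f = ls + config@lambda * tv,
       gradient = gradLS + config@lambda * gtv,
       ls = ls, tv = tv, Ax = Ax, gradLS = gradLS)
}

#' Chunked smoothed-TV value
#'
#' Evaluates [tvValue()] over Z-chunks, each extended by one halo slice so
#' the forward differences at chunk borders are exact; equals the unchunked
#' value to roundoff for any chunk size.
#'
#' @inheritParams tvValue
#' @param chunkSlices slices per chunk, in `[1, Nz]`.
#' @return scalar.
#' @export
tvChunked <- function(x, beta, chunkSlices, anisotropy = 1) {
  v <- asVolumeValues(x)
  Nz <- dim(v)[3]
  stopifnot(chunkSlices >= 1L, chunkSlices <= Nz)
  total <- 0
  for (k0 in seq(1L, Nz, by = chunkSlices)) {
    k1 <- min(k0 + chunkSlices - 1L, Nz)
    kHalo <- min(k1 + 1L, Nz)              # one halo slice after the chunk
    sub <- v[, , k0:kHalo, drop = FALSE]
    u <- fwdDiff(sub, 1L); vy <- fwdDiff(sub, 2L)
    w <- fwdDiff(sub, 3L)
    if (k1 == Nz && kHalo == Nz) {
      # last chunk: the global replicate boundary is the local one
    } else if (kHalo > k1) {
      # drop halo-slice terms; they belong to the next chunk
      keep <- seq_len(k1 - k0 + 1L)
      u <- u[, , keep, drop = FALSE]; vy <- vy[, , keep, drop = FALSE]
      w <- w[, , keep, drop = FALSE]
    }
    total <- total + sum(sqrt(u^2 + vy^2 + (anisotropy * w)^2 + beta^2))
  }
  total
}

# Chunked TV gradient: one halo slice on each side of the chunk. A kept
# plane's gradient depends on x at planes k-1, k, k+1 only, and the local
# replicate boundary of the halo block coincides with the global one exactly
# where it matters (halo planes are discarded), so the per-voxel arithmetic
# is identical to tvGradient and the result matches bitwise.
tvGradientChunked <- function(x, beta, chunkSlices, anisotropy = 1) {
  v <- asVolumeValues(x)
  Nz <- dim(v)[3]
  stopifnot(chunkSlices >= 1L, chunkSlices <= Nz)
  out <- array(0, dim = dim(v))
  for (k0 in seq(1L, Nz, by = chunkSlices)) {
    k1 <- min(k0 + chunkSlices - 1L, Nz)
    lo <- max(1L, k0 - 1L)
    hi <- min(Nz, k1 + 1L)
    gsub <- tvGradient(v[, , lo:hi, drop = FALSE], beta, anisotropy)
    out[, , k0:k1] <- gsub[, , (k0 - lo + 1L):(k1 - lo + 1L), drop = FALSE]
  }
  out
}

#' Sweep the regularization weight
#'
#' Runs [sgpSolve()] over a grid of `lambda` values and reports the recovery
#' error of each reconstruction against a ground-truth volume -- the
#' trial-and-error tuning such models require, made explicit.
#'
#' @param b a [ProjectionStack-class].
#' @param geometry,grid acquisition description.
#' @param truth ground-truth [Volume-class].
#' @param lambdas numeric vector of candidate weights.
#' @param iters iterations per candidate.
#' @param ... further arguments to [objectiveConfig()] / [sgpSolve()].
#' @return data.frame with columns `lambda` and `recoveryError`.
#' @export
tuneLambda <- function(b, geometry, grid, truth, lambdas, iters = 15L, ...) {
  err <- vapply(lambdas, function(l) {
    cfg <- objectiveConfig(lambda = l, ...)
    fit <- sgpSolve(b, geometry, grid, cfg,
                    solverConfig(maxiter = as.integer(iters)))
    recoveryError(fit$x, truth)
  }, numeric(1))
  data.frame(lambda = lambdas, recoveryError = err)
}
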