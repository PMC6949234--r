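#' Solver configuration
#'
#' Canonical settings for the scaled gradient projection iteration. The
#' stopping rule is `|f(x_k) - f(x_{k-1})| < tol * |f(x_k)|` or
#' `k > maxiter`.
#'
#' @param sigma Armijo parameter in (0, 1); default 1e-4.
#' @param gamma backtracking shrink in (0, 1); default 0.4.
#' @param alphaMin,alphaMax steplength bounds; defaults 1e-10 and 1e5.
#' @param alpha0 initial steplength; default 1.3.
#' @param maxiter iteration cap; default 100.
#' @param tol relative objective-change tolerance; default 1e-6.
#' @param bbMemory number of recent BB2 steps remembered; default 2.
#' @param bbTau initial Barzilai-Borwein switching threshold; default 0.5.
#' @param seed seed for any randomized initialization; default 1.
#' @return a [SolverConfig-class].
#' @export
solverConfig <- function(sigma = 1e-4, gamma = 0.4, alphaMin = 1e-10,
                         alphaMax = 1e5, alpha0 = 1.3, maxiter = 100L,
                         tol = 1e-6, bbMemory = 2L, bbTau = 0.5,
                         seed = 1L) {
  new("SolverConfig", sigma = sigma, gamma = gamma, alphaMin = alphaMin,
      alphaMax = alphaMax, alpha0 = alpha0, maxiter = as.integer(maxiter),
      tol = tol, bbMemory = as.integer(bbMemory), bbTau = bbTau,
      seed = as.integer(seed))
}

#' Projection onto the nonnegative orthant
#'
#' Elementwise `max(v, 0)`; idempotent.
#'
#' @param v a [Volume-class] or numeric array.
#' @return same type as the input.
#' @export
projectNonneg <- function(v) {
  if (is(v, "Volume")) volume(pmax(v@values, 0), v@grid) else pmax(v, 0)
}

#' Scaling-bound update
#'
#' `rho_{k+1} = sqrt(1 + 1e15 / (k + 1)^2.1)`: very loose bounds on the
#' scaling matrix in the first iterations, decreasing monotonically to 1 so
#' the scaling matrix is asymptotically forced to the identity (a
#' convergence requirement of the method).
#'
#' @param k iteration counter (>= 0).
#' @return scalar > 1.
#' @export
updateRho <- function(k) {
  stopifnot(k >= 0)
  sqrt(1 + 1e15 / (k + 1)^2.1)
}

#' Diagonal scaling matrix from the gradient splitting
#'
#' With the gradient split as `grad f = V - U`, `V >= 0` (the positive
#' part collecting `A^T A x` and the positive TV terms), the diagonal is
#' `D_jj = clip(x_j / V_j, 1/rho, rho)`, with `D_jj = 1` wherever
#' `x_j = 0` or `V_j = 0`.
#'
#' @param x current iterate ([Volume-class] or array), nonnegative.
#' @param posPart the positive part V (same shape), nonnegative.
#' @param rho scaling bound (>= 1).
#' @return numeric array: the diagonal of D.
#' @export
scalingMatrix <- function(x, posPart, rho) {
  stopifnot(rho >= 1)
  xv <- asVolumeValues(x); V <- asVolumeValues(posPart)
  if (any(V < 0)) stop("posPart: must be elementwise nonnegative")
  D <- array(1, dim = dim(xv))
  ok <- xv > 0 & V > 0
  D[ok] <- pmin(pmax(xv[ok] / V[ok], 1 / rho), rho)
  D
}

#' Scaled Barzilai-Borwein steplength with adaptive alternation
#'
#' Computes the two scaled BB values
#' `BB1 = <D^-1 s, D^-1 s> / <D^-1 s, z>` and
#' `BB2 = <s, D z> / <D z, D z>` from the last step `s = x_k - x_{k-1}` and
#' gradient change `z = grad_k - grad_{k-1}`. A nonpositive curvature
#' denominator makes the corresponding rule fall back to `alphaMax`. The
#' alternation keeps a short memory of recent BB2 values: when
#' `BB2/BB1 < tau` it returns the smallest remembered BB2 and shrinks
#' `tau` by 0.9, otherwise it returns BB1 and grows `tau` by 1.1. The
#' result is clipped to `[alphaMin, alphaMax]`.
#'
#' @param s,z difference arrays of the same shape.
#' @param Ddiag diagonal of the scaling matrix (same shape).
#' @param alphaPrev previous steplength (kept for interface completeness).
#' @param config a [SolverConfig-class].
#' @param state alternation state: `list(tau = ..., history = ...)`;
#'   defaults to a fresh state from `config`.
#' @return list with `alpha`, and the updated `state`.
#' @export
bbSteplength <- function(s, z, Ddiag, alphaPrev, config,
                         state = NULL) {
  if (is.null(state)) state <- list(tau = config@bbTau, history = numeric(0))
  s <- asVolumeValues(s); z <- asVolumeValues(z)
  clip <- function(a) min(max(a, config@alphaMin), config@alphaMax)
  sD <- s / Ddiag
  den1 <- sum(sD * z)
  alpha1 <- if (den1 <= 0) config@alphaMax else clip(sum(sD * sD) / den1)
  Dz <- Ddiag * z
  num2 <- sum(s * Dz)
  den2 <- sum(Dz * Dz)
  alpha2 <- if (num2 <= 0 || den2 <= 0) config@alphaMax else
    clip(num2 / den2)
  history <- c(state$history, alpha2)
  if (length(history) > config@bbMemory)
    history <- tail(history, config@bbMemory)
  if (alpha2 / alpha1 < state$tau) {
    alpha <- min(history)
    tau <- state$tau * 0.9
  } else {
    alpha <- alpha1
    tau <- state$tau * 1.1
  }
  list(alpha = clip(alpha), state = list(tau = tau, history = history))
}

#' Armijo backtracking line search
#'
#' Starting from `eta = 1`, shrinks by `gamma` until
#' `f(x + eta d) <= f(x) + sigma * eta * <grad f(x), d>`. The evaluator is
#' expected to be cheap per trial (with the forward projection of `x` and
#' `d` cached, each trial re-evaluates only vector arithmetic and the TV
#' term).
#'
#' @param fX objective value at the current iterate.
#' @param gradDotD directional derivative `<grad f(x), d>`; must be < 0.
#' @param fEvaluator function of `eta` returning `f(x + eta d)`.
#' @param config a [SolverConfig-class].
#' @return list with the accepted `eta`, `fNew`, and the number of `trials`.
#' @export
backtrack <- function(fX, gradDotD, fEvaluator, config) {
  if (!(gradDotD < 0))
    stop("gradDotD: not a descent direction (<grad, d> must be < 0)")
  eta <- 1
  trials <- 0L
  repeat {
    fNew <- fEvaluator(eta)
    if (fNew <= fX + config@sigma * eta * gradDotD)
      return(list(eta = eta, fNew = fNew, trials = trials + 1L))
    eta <- config@gamma * eta
    trials <- trials + 1L
    if (trials > 60L)
      stop("backtracking underflow: no sufficient decrease after 60 ",
           "shrinks; the gradient is likely inconsistent with the objective")
  }
}

#' Stopping rule
#'
#' TRUE iff `|f_k - f_prev| < tol * |f_k|` or `k > maxiter` (strict
#' inequalities).
#'
#' @param fK,fPrev objective at the current and previous iterate.
#' @param k iteration counter (>= 1).
#' @param config a [SolverConfig-class].
#' @return logical.
#' @export
stopCheck <- function(fK, fPrev, k, config) {
  stopifnot(k >= 1)
  (abs(fK - fPrev) < config@tol * abs(fK)) || (k > config@maxiter)
}

#' Scaled gradient projection reconstruction
#'
#' Minimizes `f(x) = 1/2 ||Ax - b||^2 + lambda TV_beta(x)` over `x >= 0` by
#' the five-step SGP iteration: (1) scaled projected direction
#' `d = P_+(x - alpha D grad f(x)) - x`; (2) Armijo backtracking along `d`;
#' (3) iterate update `x <- x + eta d`; (4) scaling-bound and scaling-matrix
#' update from the gradient splitting; (5) adaptive Barzilai-Borwein
#' steplength update. Iterations stop by [stopCheck()].
#'
#' The start is `x0 = P_+(A^T b)` rescaled so `||A x0|| = ||b||` -- a
#' geometry-aware, deterministic initialization. Each iteration costs one
#' forward and one backward projection; backtracking trials reuse the cached
#' projections of `x` and `d` and re-evaluate only the TV term.
#' All reductions run in a fixed order, so runs are bitwise reproducible.
#'
#' @param b a [ProjectionStack-class].
#' @param geometry a [ScanGeometry-class]; defaults to `geometry(b)`.
#' @param grid a [VolumeGrid-class].
#' @param objConfig an [ObjectiveConfig-class].
#' @param solverCfg a [SolverConfig-class].
#' @param checkpoints integer iterations at which to snapshot the iterate
#'   (e.g. `c(4, 12, 30)`).
#' @param chunkSlices optional Z-chunk size for projections and TV.
#' @param logFile optional CSV path; the iteration log (iteration, f, data
#'   term, TV term, eta, alpha, rho) is streamed there.
#' @param x0 optional starting [Volume-class] (nonnegative); overrides the
#'   default initialization.
#' @return list with `x` (the reconstruction, [Volume-class]), and `state`:
#'   a list holding `fHistory`, `alpha`, `rho`, `s`, `z`, `k`, `etaLast`,
#'   `rhoHistory`, `alphaHistory`, `Dmin`, `Dmax` (per-iteration scaling
#'   extremes), `checkpoints` (named list of [Volume-class] snapshots),
#'   `log` (data.frame) and `converged`.
#' @export
sgpSolve <- function(b, grid, objConfig, solverCfg = solverConfig(),
                     geometry = NULL, checkpoints = integer(0),
                     chunkSlices = NULL, logFile = NULL, x0 = NULL) {
  if (is.null(geometry)) geometry <- b@geometry
  validateScan(geometry, grid)
  lambda <- objConfig@lambda

  ATb <- backProject(b, grid, geometry, chunkSlices = chunkSlices)
  if (is.null(x0)) {
    x <- projectNonneg(ATb@values)
    Ax <- forwardProject(volume(x, grid), geometry, grid,
                         chunkSlices = chunkSlices)
    nb <- sqrt(sum(b@values^2)); nAx <- sqrt(sum(Ax@values^2))
    if (nAx > 0) {
      sc <- nb / nAx
      x <- x * sc
      Ax <- projectionStack(Ax@values * sc, geometry)
    }
  } else {
    if (any(x0@values < 0)) stop("x0: must be nonnegative")
    x <- x0@values
    Ax <- forwardProject(x0, geometry, grid, chunkSlices = chunkSlices)
  }

  ev <- objectiveGradient(volume(x, grid), b, objConfig, geometry, grid,
                          Ax = Ax, chunkSlices = chunkSlices)
  f <- ev$f; grad <- ev$gradient
  alpha <- solverCfg@alpha0
  rho <- sqrt(1 + 1e15)          # initial bound; D0 is the identity
  D <- array(1, dim = grid@dims)
  bbState <- NULL
  fHistory <- f
  rhoHistory <- numeric(0); alphaHistory <- numeric(0)
  Dmin <- numeric(0); Dmax <- numeric(0)
  etaLast <- NA_real_
  snaps <- list()
  logRows <- list()
  converged <- FALSE
  sArr <- NULL; zArr <- NULL
  k <- 0L

  while (k < solverCfg@maxiter) {
    d <- pmax(x - alpha * D * grad, 0) - x
    gd <- sum(grad * d)
    if (all(d == 0)) { converged <- TRUE; break }
    # a directional derivative at roundoff level cannot produce a decrease
    # the Armijo test can resolve: the iterate is numerically stationary
    if (gd >= -.Machine$double.eps * max(abs(f), 1)) {
      converged <- TRUE; break
    }
    Ad <- forwardProject(volume(d, grid), geometry, grid,
                         chunkSlices = chunkSlices)
    residBase <- Ax@values - b@values
    fEval <- function(eta) {
      r <- residBase + eta * Ad@values
      xt <- x + eta * d
      tv <- if (is.null(chunkSlices))
        tvValue(xt, objConfig@beta, objConfig@anisotropy)
      else tvChunked(xt, objConfig@beta, chunkSlices, objConfig@anisotropy)
      0.5 * sum(r^2) + lambda * tv
    }
    bt <- backtrack(f, gd, fEval, solverCfg)
    eta <- bt$eta
    xNew <- pmax(x + eta * d, 0)   # exact feasibility despite roundoff
    AxNew <- projectionStack(Ax@values + eta * Ad@values, geometry)
    evNew <- objectiveGradient(volume(xNew, grid), b, objConfig, geometry,
                               grid, Ax = AxNew, chunkSlices = chunkSlices)
    sArr <- xNew - x
    zArr <- evNew$gradient - grad

    rho <- updateRho(k)
    Vls <- pmax(evNew$gradLS + ATb@values, 0)  # A^T A x, clipped at 0
    Vtv <- tvSplitPositive(xNew, objConfig@beta, objConfig@anisotropy)
    D <- scalingMatrix(xNew, Vls + lambda * Vtv, rho)
    bbRes <- bbSteplength(sArr, zArr, D, alpha, solverCfg, bbState)
    alpha <- bbRes$alpha; bbState <- bbRes$state

    k <- k + 1L
    fPrev <- f
    x <- xNew; Ax <- AxNew; grad <- evNew$gradient; f <- bt$fNew
    fHistory <- c(fHistory, f)
    rhoHistory <- c(rhoHistory, rho)
    alphaHistory <- c(alphaHistory, alpha)
    Dmin <- c(Dmin, min(D)); Dmax <- c(Dmax, max(D))
    etaLast <- eta
    logRows[[k]] <- data.frame(iteration = k, f = f, ls = evNew$ls,
                               tv = evNew$tv, eta = eta, alpha = alpha,
                               rho = rho)
    if (k %in% checkpoints)
      snaps[[paste0("iter", k)]] <- volume(x, grid)
    if (stopCheck(f, fPrev, k, solverCfg)) { converged <- TRUE; break }
  }

  log <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame(iteration = integer(0), f = numeric(0), ls = numeric(0),
               tv = numeric(0), eta = numeric(0), alpha = numeric(0),
               rho = numeric(0))
  if (!is.null(logFile)) utils::write.csv(log, logFile, row.names = FALSE)
  if (any(!is.finite(fHistory)))
    stop("objective became non-finite; check geometry scaling and lambda")
  list(x = volume(x, grid),
       state = list(fHistory = fHistory, alpha = alpha, rho = rho,
                    s = sArr, z = zArr, k = k, etaLast = etaLast,
                    rhoHistory = rhoHistory, alphaHistory = alphaHistory,
                    Dmin = Dmin, Dmax = Dmax,
                    checkpoints = snaps, log = log, converged = converged))
}
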