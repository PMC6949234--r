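test_that("nonnegative projection clips, preserves, and is idempotent", {
  vg <- smallGrid(c(3, 1, 1))
  v <- volume(array(c(-1, 0.5, 0), dim = c(3, 1, 1)), vg)
  p <- projectNonneg(v)
  expect_equal(as.numeric(values(p)), c(0, 0.5, 0))
  expect_identical(values(projectNonneg(p)), values(p))
  expect_identical(projectNonneg(c(2, 3)), c(2, 3))
})

test_that("the scaling bound follows its closed form and decays to 1", {
  expect_equal(updateRho(0), sqrt(1 + 1e15))
  expect_equal(updateRho(0), 3.16227766e7, tolerance = 1e-8)
  r <- vapply(0:100, updateRho, numeric(1))
  expect_true(all(diff(r) < 0))
  expect_gt(updateRho(1e9), 1)
  expect_lt(updateRho(1e9) - 1, 1e-4)
})

test_that("the scaling matrix clips x/V into [1/rho, rho] with unit fallbacks", {
  D <- scalingMatrix(array(2, c(1, 1, 1)), array(1, c(1, 1, 1)), 10)
  expect_equal(as.numeric(D), 2)
  D <- scalingMatrix(array(100, c(1, 1, 1)), array(1, c(1, 1, 1)), 10)
  expect_equal(as.numeric(D), 10)
  D <- scalingMatrix(array(0.001, c(1, 1, 1)), array(1, c(1, 1, 1)), 10)
  expect_equal(as.numeric(D), 0.1)
  # x = 0 or V = 0 give the identity entry
  D <- scalingMatrix(array(c(0, 5), c(2, 1, 1)), array(c(3, 0), c(2, 1, 1)),
                     10)
  expect_equal(as.numeric(D), c(1, 1))
  expect_error(scalingMatrix(array(1, c(1, 1, 1)),
                             array(-1, c(1, 1, 1)), 10), "nonnegative")
  set.seed(91)
  x <- array(runif(60), c(5, 4, 3)); V <- array(runif(60), c(5, 4, 3))
  for (rho in c(1.5, 3, 50)) {
    D <- scalingMatrix(x, V, rho)
    expect_true(all(D >= 1 / rho - 1e-15 & D <= rho + 1e-15))
  }
})

test_that("BB steplengths reproduce hand-computed values and fallbacks", {
  cfg <- solverConfig(alphaMin = 1e-10, alphaMax = 1e5)
  one <- array(1, c(2, 1, 1))
  s <- array(c(1, -2), c(2, 1, 1))

  # z = s, D = I: both rules give 1
  expect_equal(bbSteplength(s, s, one, 1, cfg)$alpha, 1)

  # nonpositive curvature: fall back to alphaMax
  expect_equal(bbSteplength(s, -s, one, 1, cfg)$alpha, cfg@alphaMax)

  # quadratic f = x' diag(1,4) x / 2, one gradient step from (1,1) with
  # alpha 0.1: s = (-0.1, -0.4), z = (-0.1, -1.6); by explicit arithmetic
  # BB1 = <s,s>/<s,z> = 0.17/0.65, BB2 = <s,z>/<z,z> = 0.65/2.57
  s <- array(c(-0.1, -0.4), c(2, 1, 1))
  z <- array(c(-0.1, -1.6), c(2, 1, 1))
  bb1 <- 0.17 / 0.65; bb2 <- 0.65 / 2.57
  # ratio bb2/bb1 = 0.967 >= tau = 0.5: BB1 is returned, tau grows
  res <- bbSteplength(s, z, one, 1, cfg)
  expect_equal(res$alpha, bb1, tolerance = 1e-14)
  expect_equal(res$state$tau, 0.5 * 1.1)
  expect_equal(res$state$history, bb2, tolerance = 1e-14)

  # forcing the alternation branch returns the smallest remembered BB2
  res2 <- bbSteplength(s, z, one, 1, cfg,
                       state = list(tau = 0.99, history = 0.9 * bb2))
  expect_equal(res2$alpha, 0.9 * bb2, tolerance = 1e-14)
  expect_equal(res2$state$tau, 0.99 * 0.9)
})

test_that("Armijo backtracking follows the printed while-loop", {
  cfg <- solverConfig(sigma = 0.25, gamma = 0.5)

  # f(x) = x^2 at x = 1 along d = -3: hand iteration gives eta = 0.5
  fev <- function(eta) (1 - 3 * eta)^2
  res <- backtrack(1, 2 * (-3), fev, cfg)
  expect_equal(res$eta, 0.5)
  expect_equal(res$fNew, 0.25)

  # a full quadratic step that already satisfies Armijo
  res1 <- backtrack(0.5, -1, function(eta) 0.5 * (1 - eta)^2, cfg)
  expect_equal(res1$eta, 1)

  # linear decrease accepts eta = 1 for any sigma < 1
  res2 <- backtrack(5, -2, function(eta) 5 - 2 * eta, cfg)
  expect_equal(res2$eta, 1)

  expect_error(backtrack(1, 0.5, fev, cfg), "descent")
  expect_error(backtrack(1, -1e-9, function(eta) 2, cfg), "underflow")
})

test_that("the stopping rule applies strict relative-change and cap criteria", {
  cfg <- solverConfig(maxiter = 50L, tol = 1e-6)
  expect_true(stopCheck(1.0, 1.0000009, 3, cfg))
  expect_false(stopCheck(1.0, 1.000002, 3, cfg))
  expect_true(stopCheck(1.0, 2.0, 51, cfg))
  expect_false(stopCheck(1.0, 2.0, 50, cfg))
})

test_that("on a permutation system SGP recovers the projected data", {
  sc <- identityScan(8)
  set.seed(4)
  bv <- array(rnorm(64), dim = c(8, 8, 1))
  b <- projectionStack(bv, sc$geometry)
  fit <- sgpSolve(b, sc$grid, objectiveConfig(lambda = 0),
                  solverConfig(maxiter = 300L, tol = 1e-15,
                               alphaMax = 1e6))
  expect_equal(values(fit$x),
               array(pmax(aperm(bv, c(2, 1, 3)), 0), dim = c(8, 8, 1)),
               tolerance = 1e-8)

  # nonnegative data are recovered exactly (unconstrained minimizer)
  bpos <- projectionStack(abs(bv), sc$geometry)
  fit2 <- sgpSolve(bpos, sc$grid, objectiveConfig(lambda = 0),
                   solverConfig(maxiter = 300L, tol = 1e-15,
                                alphaMax = 1e6))
  expect_lt(max(abs(values(fit2$x) - aperm(abs(bv), c(2, 1, 3)))), 1e-8)
})

test_that("SGP iterations respect feasibility, monotonicity and bound contracts", {
  g <- smallScan(); vg <- smallGrid(c(8, 8, 3))
  xt <- randomVolume(vg, 13)
  b <- addNoise(forwardProject(xt, g, vg), noiseSpec(40, 5))
  cfg <- solverConfig(maxiter = 40L, tol = 1e-12)
  fit <- sgpSolve(b, vg, objectiveConfig(lambda = 0.05), cfg,
                  checkpoints = c(2L, 10L))
  st <- fit$state

  expect_true(all(values(fit$x) >= 0))
  expect_true(all(diff(st$fHistory) <= 0))
  expect_equal(st$rhoHistory,
               sqrt(1 + 1e15 / seq_along(st$rhoHistory)^2.1))
  expect_true(all(st$Dmin >= 1 / st$rhoHistory - 1e-15))
  expect_true(all(st$Dmax <= st$rhoHistory + 1e-15))
  expect_true(all(st$alphaHistory >= cfg@alphaMin &
                  st$alphaHistory <= cfg@alphaMax))
  expect_named(st$checkpoints, c("iter2", "iter10"))
  expect_true(all(values(st$checkpoints$iter2) >= 0))

  # the iteration log mirrors the history
  expect_equal(st$log$f, st$fHistory[-1])
  expect_equal(st$log$rho, st$rhoHistory)

  # bitwise reproducibility of a rerun
  fit2 <- sgpSolve(b, vg, objectiveConfig(lambda = 0.05), cfg)
  expect_identical(values(fit2$x), values(fit$x))
  expect_identical(fit2$state$fHistory, st$fHistory)
})

test_that("the objective drops sharply in the first SGP iterations", {
  g <- smallScan(); vg <- smallGrid(c(8, 8, 3))
  xt <- randomVolume(vg, 17)
  b <- addNoise(forwardProject(xt, g, vg), noiseSpec(40, 6))
  long <- sgpSolve(b, vg, objectiveConfig(lambda = 0.05),
                   solverConfig(maxiter = 400L, tol = 1e-14))
  fstar <- tail(long$state$fHistory, 1)
  f0 <- long$state$fHistory[1]
  f4 <- long$state$fHistory[5]
  expect_lte(f4 - fstar, 0.25 * (f0 - fstar))
})

test_that("solver logs stream to CSV and invalid inputs are rejected", {
  g <- smallScan(); vg <- smallGrid(c(6, 6, 2))
  xt <- randomVolume(vg, 19)
  b <- forwardProject(xt, g, vg)
  logf <- tempfile(fileext = ".csv")
  fit <- sgpSolve(b, vg, objectiveConfig(lambda = 0.01),
                  solverConfig(maxiter = 5L), logFile = logf)
  lg <- read.csv(logf)
  expect_identical(names(lg),
                   c("iteration", "f", "ls", "tv", "eta", "alpha", "rho"))
  expect_equal(nrow(lg), fit$state$k)

  neg <- volume(array(-1, dim = gridDims(vg)), vg)
  expect_error(sgpSolve(b, vg, objectiveConfig(lambda = 0.01),
                        solverConfig(maxiter = 2L), x0 = neg),
               "nonnegative")
  x0 <- volume(array(1, dim = gridDims(vg)), vg)
  expect_silent(sgpSolve(b, vg, objectiveConfig(lambda = 0.01),
                         solverConfig(maxiter = 2L), x0 = x0))
})
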