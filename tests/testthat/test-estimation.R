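test_that("magnitude-ratio IVSD inverts the attenuation model and clamps noise", {
  expect_equal(ivsdFromMagnitudeRatio(1, 1, 2)$sigma, 0)
  expect_equal(ivsdFromMagnitudeRatio(1, exp(-1 / 2), 1)$sigma, 1)
  # noise pushing the encoded magnitude above the reference clamps to zero
  r <- ivsdFromMagnitudeRatio(1, 1.01, 2)
  expect_equal(r$sigma, 0)
  expect_equal(r$status, "clamped")
  # vanished signal saturates with a flag
  r2 <- ivsdFromMagnitudeRatio(1, 0, 6.28)
  expect_equal(r2$status, "saturated")
  expect_gt(r2$sigma, 0)
  expect_error(ivsdFromMagnitudeRatio(0, 1, 1), "magRef")
})

test_that("Bayesian multipoint recovers aliased and vanished-signal cases", {
  vencs <- c(0.5, 1.5, 4.5)
  kvs <- computeKv(vencs)
  # trivial zero case
  est0 <- bayesianMultipoint(forwardSignal1D(1, 0, 0, kvs), 1 + 0i, vencs)
  expect_equal(est0$vProj, 0, tolerance = 1e-6)
  expect_equal(est0$sigma, 0, tolerance = 1e-6)
  # 0.5-VENC phase aliased at v = 0.9; the joint likelihood resolves it
  est1 <- bayesianMultipoint(forwardSignal1D(1, 0.9, 0.1, kvs), 1 + 0i, vencs)
  expect_equal(est1$vProj, 0.9, tolerance = 5e-3)
  expect_equal(est1$sigma, 0.1, tolerance = 5e-3)
  # sigma = 0.6 kills the 0.5-VENC magnitude; the 1.5-VENC point carries it
  expect_lt(Mod(forwardSignal1D(1, 0.2, 0.6, kvs[1])), 1e-3)
  est2 <- bayesianMultipoint(forwardSignal1D(1, 0.2, 0.6, kvs), 1 + 0i, vencs)
  expect_equal(est2$sigma, 0.6, tolerance = 5e-3)
  expect_equal(est2$vProj, 0.2, tolerance = 5e-3)
  # degenerate input reports no-estimate
  expect_equal(bayesianMultipoint(c(0i, 0i, 0i), 0i, vencs)$status,
               "no-estimate")
})

test_that("tensor solve inverts the quadratic design exactly and is linear", {
  D <- buildDirections()
  rho <- 1060
  # isotropy: equal variances give rho*c*I
  expect_equal(solveRst(rep(0.04, 6), D, rho), rho * 0.04 * diag(3))
  # diagonal tensor: face-diagonal directions observe the average variance
  Rd <- diag(c(0.09, 0.04, 0.01)) * rho
  s2 <- as.numeric(quadraticDesign(D) %*%
                     c(0.09, 0.04, 0.01, 0, 0, 0))
  expect_equal(s2[4], (0.09 + 0.04) / 2)
  expect_equal(solveRst(s2, D, rho), Rd)
  # random PSD round-trips to numerical precision
  for (i in 1:5) {
    R <- randomPsdTensor(120, seed = 70 + i)
    s2 <- as.numeric(quadraticDesign(D) %*%
                       c(R[1, 1], R[2, 2], R[3, 3], R[1, 2], R[1, 3],
                         R[2, 3])) / rho
    expect_lt(relErr(solveRst(s2, D, rho), R), 1e-10)
    # linearity in sigma^2
    expect_equal(solveRst(2.5 * s2, D, rho), 2.5 * solveRst(s2, D, rho))
  }
  expect_error(solveRst(rep(1, 6), matrix(rep(c(1, 0, 0), 6), ncol = 3,
                                          byrow = TRUE), rho),
               "rank")
})

test_that("mean-velocity solve matches the normal-equations oracle", {
  D <- buildDirections()
  v <- c(1, 0, 0)
  proj <- as.numeric(D %*% v)
  expect_equal(proj[4], 1 / sqrt(2))
  expect_equal(solveMeanVelocity(proj, D), v)
  set.seed(8)
  for (i in 1:5) {
    v <- rnorm(3)
    expect_equal(solveMeanVelocity(as.numeric(D %*% v), D), v)
    # noisy projections: explicit (A^T A)^{-1} A^T oracle
    noisy <- as.numeric(D %*% v) + rnorm(6, 0, 0.05)
    oracle <- as.numeric(solve(t(D) %*% D) %*% t(D) %*% noisy)
    expect_equal(solveMeanVelocity(noisy, D), oracle)
  }
  expect_error(solveMeanVelocity(c(1, 2), D[1:2, ]), "rank 3|directions")
})

test_that("single-VENC Monte Carlo shows small bias near the optimum and a plateau", {
  venc <- 0.5
  tab <- monteCarloIvsdUncertainty(venc, c(venc / pi, 0), snr = 40,
                                   nSamples = 2000, seed = 4)
  near <- tab[tab$sigmaTrue > 0, ]
  expect_lt(abs(near$mean - venc / pi) / (venc / pi), 0.02)
  # sigma = 0 keeps the estimator non-negative
  expect_gte(tab$mean[tab$sigmaTrue == 0], 0)
})

test_that("noise worsens the sigma estimate monotonically with decreasing SNR", {
  venc <- 1.5
  sTrue <- venc / pi
  rmse <- sapply(c(40, 30, 20), function(snr) {
    tab <- monteCarloIvsdUncertainty(venc, sTrue, snr = snr,
                                     nSamples = 3000, seed = 17)
    sqrt((tab$mean - sTrue)^2 + tab$sd^2)
  })
  expect_true(all(diff(rmse) > 0))
})

test_that("whole-stack estimation recovers a noiseless phantom on both paths", {
  ph <- tinyPhantom()
  st <- tinyStack()
  estB <- estimateStack(st, rho = fluidDensity(ph))
  expect_lt(relErr(estB$rst, rstTensor(ph)), 1e-3)
  expect_lt(max(abs(estB$vMean - meanVelocity(ph))), 1e-4)
  estR <- estimateStack(st, rho = fluidDensity(ph), method = "ratio")
  expect_lt(relErr(estR$rst, rstTensor(ph)), 1e-10)
  expect_lt(max(abs(estR$vMean - meanVelocity(ph))), 1e-10)
  expect_true(all(estB$quality[lumenMask(ph)] %in% c(0L, 1L)))
})
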