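test_that("1-d signal model matches the analytic attenuation and phase", {
  # zero-fluctuation identity
  expect_equal(forwardSignal1D(1, 0, 0, 3.7), 1 + 0i)
  # analytic magnitude at sigma = kv = 1
  expect_equal(Mod(forwardSignal1D(1, 0, 1, 1)), exp(-1 / 2))
  # phase-wrap boundary: v = VENC gives phase -pi
  venc <- 0.8
  expect_equal(Arg(forwardSignal1D(1, venc, 0, pi / venc)), -pi)
  # negative sigma rejected
  expect_error(forwardSignal1D(1, 0, -0.1, 1), "sigma")
})

test_that("magnitude is monotone non-increasing in sigma and in diagonal RST", {
  kv <- computeKv(1.5)
  mags <- Mod(forwardSignal1D(1, 0.3, seq(0, 1, by = 0.05), kv))
  expect_true(all(diff(mags) <= 0))
  # strictly decreasing in each diagonal entry when kv has a component there
  enc <- encodingVector(c(1, 1, 0), 1.0)
  base <- diag(c(50, 60, 70))
  for (axis in 1:2) {
    R2 <- base; R2[axis, axis] <- R2[axis, axis] + 25
    m1 <- Mod(forwardSignalTensor(1, voxelFlowState(c(0, 0, 0), base), enc))
    m2 <- Mod(forwardSignalTensor(1, voxelFlowState(c(0, 0, 0), R2), enc))
    expect_lt(m2, m1)
  }
})

test_that("tensor model reduces to the 1-d model and is rotation invariant", {
  rho <- 1060
  # zero tensor: magnitude preserved for every encoding
  st0 <- voxelFlowState(c(0.4, -0.2, 1), matrix(0, 3, 3), rho)
  for (v in c(0.5, 1.5, 4.5))
    expect_equal(Mod(forwardSignalTensor(2, st0, encodingVector(c(0, 1, 1), v))), 2)
  # isotropic tensor equals the 1-d model along any direction
  sigma <- 0.35
  stIso <- voxelFlowState(c(0, 0, 0), rho * sigma^2 * diag(3), rho)
  set.seed(1)
  for (i in 1:5) {
    d <- rnorm(3); enc <- encodingVector(d, 1.5)
    expect_equal(forwardSignalTensor(1, stIso, enc),
                 forwardSignal1D(1, 0, sigma, computeKv(1.5)))
  }
  # rank-1 tensor along the encoding direction equals the 1-d model
  d <- c(1, 0, 0)
  stR1 <- voxelFlowState(c(0.3, 0, 0), rho * sigma^2 * (d %o% d), rho)
  enc <- encodingVector(d, 0.9)
  expect_equal(forwardSignalTensor(1, stR1, enc),
               forwardSignal1D(1, 0.3, sigma, computeKv(0.9)))
  # joint rotation of R and kv leaves the magnitude unchanged
  for (i in 1:5) {
    R <- randomPsdTensor(150, seed = 40 + i)
    Q <- randomRotation(seed = 50 + i)
    d <- rnorm(3)
    m1 <- Mod(forwardSignalTensor(1, voxelFlowState(c(0, 0, 0), R),
                                  encodingVector(d, 1.2)))
    m2 <- Mod(forwardSignalTensor(1, voxelFlowState(c(0, 0, 0), Q %*% R %*% t(Q)),
                                  encodingVector(as.numeric(Q %*% d), 1.2)))
    expect_equal(m1, m2)
  }
  # non-symmetric tensor rejected
  bad <- matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)
  expect_error(forwardSignalTensor(1, voxelFlowState(c(0, 0, 0), bad),
                                   encodingVector(c(1, 0, 0), 1)),
               "symmetric")
})

test_that("SNR follows the 20 log10 definition and round-trips through noise", {
  expect_equal(snrDb(31.6228, 1), 30, tolerance = 1e-4)
  expect_equal(snrDb(1, 1), 0)
  expect_error(snrDb(1, 0), "noiseSd")
  expect_error(snrDb(-1, 1), "signalLevel")
  # draw noise for a 30 dB target and re-estimate the SNR from the samples
  sd0 <- noiseSdForSnr(1, 30)
  z <- complexNoise(1e6, sd0, seed = 99)
  sdHat <- sd(c(Re(z), Im(z)))
  expect_equal(snrDb(1, sdHat), 30, tolerance = 0.1)
})
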