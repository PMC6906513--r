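test_that("golden-angle masks are deterministic with the stated budget and center", {
  dims <- c(16L, 16L)
  m <- goldenAngleMask(dims, linesPerFrame = 32L, nFrames = 12L)
  counts <- apply(m, 3, sum)
  expect_true(all(counts == 32L))
  # center sampled in every frame
  expect_true(all(m[9, 9, ]))
  # acceleration factor = total / sampled
  expect_equal(prod(dims) / counts[1], 8)
  # deterministic construction
  expect_identical(m, goldenAngleMask(dims, 32L, 12L))
  # full budget gives fully sampled frames
  full <- goldenAngleMask(dims, prod(dims), 2L)
  expect_true(all(full))
})

test_that("view sharing fills frames to the cap without touching acquired lines", {
  dims <- c(8L, 8L)
  mask <- array(FALSE, c(dims, 2L, 3L))
  mask[, , , 2] <- TRUE          # middle respiratory state fully sampled
  mask[1, 1, , 1] <- TRUE        # state 1 has one acquired point
  dat <- array(0 + 0i, c(4L, dims, 2L, 3L))
  dat[, , , , 2] <- 1 + 0i
  dat[, 1, 1, , 1] <- 5 + 0i
  b <- binnedKSpace(dat, mask)
  vs <- viewShare(b, maxAcceleration = 4)
  acc <- frameAcceleration(vs)
  expect_true(all(acc <= 4))
  # already-compliant frames unchanged
  expect_equal(sum(samplingMask(vs)[, , 1, 2]), 64L)
  expect_equal(sum(sharedMask(vs)[, , 1, 2]), 0L)
  # an acquired line is never overwritten by sharing
  expect_equal(kspaceData(vs)[1, 1, 1, 1, 1], 5 + 0i)
  expect_false(sharedMask(vs)[1, 1, 1, 1])
  # borrowed points are flagged and filled exactly to the cap
  need <- ceiling(64 / 4)
  expect_equal(sum(samplingMask(vs)[, , 1, 1]), need)
  expect_equal(sum(sharedMask(vs)[, , 1, 1]), need - 1L)
})

test_that("Casorati blocks have the documented shape and lossless round-trip", {
  set.seed(6)
  series <- array(complex(real = rnorm(4^3 * 25 * 4),
                          imaginary = rnorm(4^3 * 25 * 4)),
                  c(4, 4, 4, 25, 4))
  M <- buildCasorati(series, c(1, 1, 1), 4L)
  expect_equal(dim(M), c(64L, 100L))
  # cardiac-major column order: entry (hp, rs) sits in column (rs-1)*25+hp
  expect_equal(M[, 3], as.vector(series[, , , 3, 1]))
  expect_equal(M[, 25 + 2], as.vector(series[, , , 2, 2]))
  # reshape round-trip
  expect_equal(array(M, c(4, 4, 4, 25, 4)), series)
  # constant-in-time series has rank 1
  cs <- array(rep(as.vector(series[, , , 1, 1]), 8), c(4, 4, 4, 4, 2))
  expect_equal(sum(svd(buildCasorati(cs, c(1, 1, 1), 4L))$d > 1e-10), 1L)
  expect_error(buildCasorati(series, c(2, 1, 1), 4L), "bounds")
})

test_that("singular-value thresholding matches the full-SVD oracle", {
  set.seed(7)
  for (i in 1:5) {
    M <- matrix(complex(real = rnorm(96), imaginary = rnorm(96)), 12, 8)
    tau <- runif(1, 0.1, 3)
    s <- svd(M)
    oracle <- s$u %*% (pmax(s$d - tau, 0) * Conj(t(s$v)))
    expect_lt(max(Mod(svtShrink(M, tau) - oracle)), 1e-10)
    # the proximal step never increases the nuclear norm
    expect_lt(sum(svd(svtShrink(M, tau))$d), sum(s$d))
  }
  expect_identical(svtShrink(diag(3), 0), diag(3))
})

test_that("LLR reconstruction: data-consistency limit and monotone objective", {
  dp <- dynamicRankPhantom(dims = c(12, 12, 12), nPhases = 4, nStates = 2,
                           seed = 5)
  # lambda = 0 with full sampling returns the inverse FFT solution
  ksFull <- kspaceFromSeries(dp$series, array(TRUE, c(12, 12, 4, 2)))
  rec <- llrReconstruct(ksFull, cfg = llrConfig(blockSize = 4, lambda = 0,
                                                maxIter = 3, tol = 0))
  expect_lt(max(Mod(rec$image - dp$series)), 1e-8)
  # plain proximal gradient: objective monotone non-increasing per iteration
  msk <- goldenAngleMask(c(12, 12), 36L, 8L)
  ks <- kspaceFromSeries(dp$series, msk)
  rec2 <- llrReconstruct(ks, cfg = llrConfig(blockSize = 4, lambda = 0.01,
                                             maxIter = 25, tol = 0))
  expect_true(all(diff(rec2$objective) <= 1e-9 * abs(rec2$objective[1])))
  # the nuclear-norm term decreases under the proximal step
  expect_lt(rec2$objective[length(rec2$objective)], rec2$objective[1])
})

test_that("reconstruction error decreases with lighter undersampling", {
  dp <- dynamicRankPhantom(dims = c(16, 16, 16), nPhases = 8, nStates = 4,
                           seed = 3)
  errs <- sapply(c(8L, 4L, 2L), function(acc) {
    msk <- goldenAngleMask(c(16, 16), 256L %/% acc, 32L)
    ks <- kspaceFromSeries(dp$series, msk)
    rec <- llrReconstruct(ks, cfg = llrConfig(blockSize = 8, lambda = 0.005,
                                              lambdaStart = 0.5,
                                              maxIter = 80, tol = 0,
                                              accelerate = TRUE),
                          objectiveEvery = 0L)
    nrmse(rec$image, dp$series)
  })
  expect_true(all(diff(errs) < 0))
})
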