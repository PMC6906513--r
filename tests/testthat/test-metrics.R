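test_that("TKE is the half-trace in stress units and rho/2-trace in velocity units", {
  expect_equal(tke(diag(c(200, 200, 200))), 300)
  expect_equal(tke(diag(rep(0.01, 3)), units = "m2s2", rho = 1060), 15.9)
  # rotation invariance of the trace
  for (i in 1:5) {
    R <- randomPsdTensor(90, seed = 20 + i)
    Q <- randomRotation(seed = 30 + i)
    expect_equal(tke(Q %*% R %*% t(Q)), tke(R))
  }
})

test_that("MPTSS is the eigenvalue half-range and vanishes for isotropy", {
  expect_equal(mptss(diag(c(300, 200, 100))), 100)
  expect_equal(mptss(57 * diag(3)), 0)
  # random symmetric tensors against a characteristic-polynomial root oracle
  set.seed(12)
  for (i in 1:10) {
    S <- matrix(rnorm(9, sd = 50), 3); S <- (S + t(S)) / 2
    cp <- c(-det(S),
            S[1, 1] * S[2, 2] + S[1, 1] * S[3, 3] + S[2, 2] * S[3, 3] -
              S[1, 2]^2 - S[1, 3]^2 - S[2, 3]^2,
            -sum(diag(S)), 1)
    ev <- sort(Re(polyroot(cp)), decreasing = TRUE)
    expect_equal(mptss(S), (ev[1] - ev[3]) / 2, tolerance = 1e-8)
  }
  # rotation invariance
  R <- randomPsdTensor(120, seed = 5)
  Q <- randomRotation(seed = 6)
  expect_equal(mptss(Q %*% R %*% t(Q)), mptss(R))
  # PSD bound: half-range never exceeds the trace
  for (i in 1:5) {
    R <- randomPsdTensor(70, seed = 60 + i)
    expect_lte(mptss(R), sum(diag(R)))
  }
  # non-finite voxels propagate NA
  vol <- array(1, c(2, 2, 2, 6)); vol[1, 1, 1, 2] <- NaN
  expect_true(is.na(mptss(vol)[1, 1, 1]))
  expect_false(anyNA(mptss(vol)[2, , ]))
})

test_that("median filtering matches a sort-based oracle and respects the mask", {
  dims <- c(6L, 6L, 6L)
  # constant field unchanged
  cf <- array(3.5, c(dims, 2L))
  expect_equal(medianFilterRst(cf, size = 3L), cf)
  # single-voxel outlier in a constant field is replaced
  out <- cf
  out[3, 3, 3, 1] <- 100
  filt <- medianFilterRst(out, size = 3L)
  expect_equal(filt[3, 3, 3, 1], 3.5)
  # random field vs brute-force oracle (interior + boundary voxels)
  set.seed(9)
  vol <- array(rnorm(prod(dims) * 2), c(dims, 2L))
  mask <- array(runif(prod(dims)) > 0.2, dims)
  filt <- medianFilterRst(vol, mask, size = 3L)
  oracle <- function(i, j, k, comp) {
    vals <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      ii <- min(max(i + dx, 1L), dims[1])
      jj <- min(max(j + dy, 1L), dims[2])
      kk <- min(max(k + dz, 1L), dims[3])
      if (mask[ii, jj, kk]) vals <- c(vals, vol[ii, jj, kk, comp])
    }
    median(vals)
  }
  idx <- which(mask, arr.ind = TRUE)
  set.seed(10)
  for (row in sample(nrow(idx), 25)) {
    i <- idx[row, 1]; j <- idx[row, 2]; k <- idx[row, 3]
    for (comp in 1:2)
      expect_equal(filt[i, j, k, comp], oracle(i, j, k, comp))
  }
  # voxels outside the mask pass through unchanged
  for (comp in 1:2)
    expect_equal(filt[, , , comp][!mask], vol[, , , comp][!mask])
  expect_error(medianFilterRst(vol, size = 2L), "odd")
})

test_that("KDE summaries integrate to one and match a kernel-sum oracle", {
  set.seed(11)
  x <- rnorm(300, 5, 2)
  ds <- distributionSummary(x)
  expect_equal(sum(ds$density) * diff(ds$x[1:2]), 1, tolerance = 1e-3)
  expect_equal(distributionSummary(c(1, 2, 3))$mean, 2)
  expect_equal(distributionSummary(c(1, 2, 3))$sd, 1)
  # brute-force double-loop Gaussian kernel sum at a few query points
  h <- ds$bw
  for (q in ds$x[c(50, 250, 450)]) {
    oracle <- mean(exp(-(q - x)^2 / (2 * h^2))) / (h * sqrt(2 * pi))
    kde <- approx(ds$x, ds$density, xout = q)$y
    # absolute comparison: density() approximates the kernel sum by FFT
    # binning, whose absolute error is uniform over the grid
    expect_lt(abs(kde - oracle), 1e-3)
  }
  expect_error(distributionSummary(numeric(0)), "2 finite")
})

test_that("turbulence maps drop non-finite voxels from the mask", {
  vol <- array(10, c(3, 3, 3, 6))
  vol[, , , 4:6] <- 0
  vol[1, 1, 1, 1] <- Inf
  mask <- array(TRUE, c(3, 3, 3))
  maps <- turbulenceMaps(vol, mask)
  expect_false(maps$mask[1, 1, 1])
  expect_true(all(maps$tke[maps$mask] >= 0))
  expect_true(all(maps$mptss[maps$mask] >= 0))
})
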