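test_that("encoding a phantom matches the voxel-wise forward model", {
  ph <- tinyPhantom()
  st <- tinyStack()
  idx <- encodingIndex(st)
  m <- lumenMask(ph)
  # reference is s0 inside the mask, zero outside
  refVol <- stackVolumes(st)[, , , which(is.na(idx$direction))[1]]
  expect_equal(unique(refVol[m]), 1 + 0i)
  expect_equal(max(Mod(refVol[!m])), 0)
  # one encoded volume against forwardSignalTensor at a few voxels
  sch <- encodingScheme()
  j <- which(idx$direction == 4 & idx$venc == 1.5)
  vox <- which(m, arr.ind = TRUE)
  set.seed(2)
  for (row in sample(nrow(vox), 10)) {
    i <- vox[row, , drop = FALSE]
    state <- voxelFlowState(
      meanVelocity(ph)[i[1], i[2], i[3], ],
      turbmri:::rstVecToMat(rstTensor(ph)[i[1], i[2], i[3], ]),
      fluidDensity(ph))
    expect_equal(stackVolumes(st)[i[1], i[2], i[3], j],
                 forwardSignalTensor(1, state,
                                     encodingVector(directions(sch)[4, ], 1.5)))
  }
  # zero-turbulence phantom: encoded magnitudes equal the reference
  z <- generateJetPhantom(dims = c(12, 12, 24), peakIvsd = 0, seed = 3)
  stz <- encodePhantom(z, sch)
  mags <- Mod(turbmri:::maskedComponents(stackVolumes(stz), lumenMask(z)))
  expect_equal(max(abs(mags - 1)), 0, tolerance = 1e-12)
  # vanished-signal regime at VENC 0.5 for IVSD 0.6
  expect_lt(Mod(forwardSignal1D(1, 0, 0.6, computeKv(0.5))), 1e-3)
})

test_that("window downsampling preserves identity, constants and the mean", {
  st <- tinyStack()
  expect_identical(windowDownsample(st, 1L), st)
  ds <- windowDownsample(st, 2L)
  expect_equal(dim(stackVolumes(ds))[1:3], dim(lumenMask(st)) / 2L)
  expect_equal(gridSpacing(ds), 2 * gridSpacing(st))
  # image-domain mean preserved (DC untouched)
  for (j in c(1L, 5L))
    expect_equal(mean(stackVolumes(ds)[, , , j]),
                 mean(stackVolumes(st)[, , , j]), tolerance = 1e-12)
  # a spatially constant volume stays constant at any factor
  cvol <- array(2 + 1i, c(8, 8, 8))
  out <- turbmri:::downsampleVolume(cvol, 2L)
  expect_equal(max(Mod(out - (2 + 1i))), 0, tolerance = 1e-12)
  # factor-4 output equals an independent crop-k-space oracle
  set.seed(4)
  vol <- array(complex(real = rnorm(16^3), imaginary = rnorm(16^3)),
               c(16, 16, 16))
  got <- turbmri:::downsampleVolume(vol, 4L)
  K <- fft(vol)
  keep <- c(1:2, 15:16)   # lowest frequencies, unshifted layout
  oracle <- fft(K[keep, keep, keep], inverse = TRUE) / length(vol)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_error(windowDownsample(st, 5L), "divide")
})

test_that("noise injection hits the target SNR and is seed-reproducible", {
  st <- tinyStack()
  nz <- addNoise(st, 30, seed = 5)
  level <- mean(Mod(turbmri:::maskedComponents(stackVolumes(st),
                                               lumenMask(st))))
  resid <- stackVolumes(nz) - stackVolumes(st)
  sdHat <- sd(c(Re(resid), Im(resid)))
  expect_equal(snrDb(level, sdHat), 30, tolerance = 0.05)
  # infinite SNR is a passthrough
  expect_identical(addNoise(st, Inf), st)
  # same seed reproduces, different seed differs with matching statistics
  nz2 <- addNoise(st, 30, seed = 5)
  expect_identical(stackVolumes(nz), stackVolumes(nz2))
  nz3 <- addNoise(st, 30, seed = 6)
  expect_false(identical(stackVolumes(nz), stackVolumes(nz3)))
  resid3 <- stackVolumes(nz3) - stackVolumes(st)
  expect_equal(sd(c(Re(resid3), Im(resid3))), sdHat, tolerance = 0.02)
})

test_that("estimation error vanishes at very high SNR on the native grid", {
  ph <- tinyPhantom()
  st <- addNoise(tinyStack(), 60, seed = 2)
  est <- estimateStack(st, rho = fluidDensity(ph))
  maps <- turbulenceMaps(est$rst, est$mask)
  truth <- turbulenceMaps(rstTensor(ph), lumenMask(ph))
  expect_lt(abs(mean(maps$tke[maps$mask]) /
                  mean(truth$tke[lumenMask(ph)]) - 1), 0.005)
})

test_that("the experiment driver reproduces the noiseless ground truth at factor 1", {
  ph <- tinyPhantom()
  sch <- encodingScheme()
  tbl <- accuracyPrecisionExperiment(ph, sch, snrList = Inf, factorList = 1L,
                                     nReps = 1L, seed = 1, medianSize = 1L,
                                     method = "ratio")
  truth <- turbulenceMaps(rstTensor(ph), lumenMask(ph))
  expect_lt(abs(tbl$tkeMean / mean(truth$tke[lumenMask(ph)]) - 1), 1e-3)
  expect_lt(abs(tbl$mptssMean / mean(truth$mptss[lumenMask(ph)]) - 1), 1e-3)
  # repetition variance shrinks with SNR (common seeds)
  tbl2 <- accuracyPrecisionExperiment(ph, sch, snrList = c(40, 25, 15),
                                      factorList = 1L, nReps = 4L, seed = 2)
  s <- summarizeExperiment(tbl2)
  spread <- s$tkeMeanSd[order(-s$snr)]
  expect_true(all(diff(spread) > 0))
})
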