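test_that("kv = pi/VENC and the optimal-VENC rule are exact inverses", {
  expect_equal(computeKv(0.5), 6.2832, tolerance = 1e-4)
  expect_equal(computeKv(1.5), 2.0944, tolerance = 1e-4)
  expect_equal(computeKv(4.5), 0.6981, tolerance = 1e-4)
  expect_error(computeKv(0), "venc")
  expect_equal(optimalVenc(0.2), 0.6283, tolerance = 1e-4)
  expect_equal(optimalVenc(0.4775), 1.50, tolerance = 1e-3)
  expect_error(optimalVenc(-1), "sigma")
  # kv * sigma = 1 at the optimum
  for (s in c(0.1, 0.3, 0.8))
    expect_equal(computeKv(optimalVenc(s)) * s, 1)
})

test_that("the canonical direction set has the stated rows and full tensor rank", {
  D <- buildDirections()
  expect_equal(D[1, ], c(1, 0, 0))
  expect_equal(D[4, ], c(1 / sqrt(2), 1 / sqrt(2), 0))
  expect_equal(unname(sqrt(rowSums(D^2))), rep(1, 6))
  expect_equal(qr(quadraticDesign(D))$rank, 6L)
})

test_that("the optimal-VENC rule matches the second-derivative criterion numerically", {
  # the optimum kv = 1/sigma is defined by the vanishing second derivative
  # of the attenuation with respect to sigma; locate the sign change by
  # numeric differentiation at sigma = 0.3
  sigma <- 0.3
  kvGrid <- seq(0.5, 12, by = 0.001)
  h <- 1e-4
  d2 <- (exp(-(sigma + h)^2 * kvGrid^2 / 2) -
           2 * exp(-sigma^2 * kvGrid^2 / 2) +
           exp(-(sigma - h)^2 * kvGrid^2 / 2)) / h^2
  kvStar <- kvGrid[which(diff(sign(d2)) != 0)[1]]
  expect_equal(kvStar, 1 / sigma, tolerance = 0.01)
  expect_equal(computeKv(optimalVenc(sigma)), 1 / sigma)
})

test_that("sensitivity curves decay as expected with VENC", {
  sg <- seq(0, 3, by = 0.01)
  expect_equal(sensitivityCurve(0.5, 0), 1)
  expect_equal(sensitivityCurve(1.5, 1.5 / pi), exp(-1 / 2))
  c05 <- sensitivityCurve(0.5, sg)
  c15 <- sensitivityCurve(1.5, sg)
  expect_true(all(diff(c05) < 0))
  # the low VENC vanishes (below 0.01) at smaller sigma than the high VENC
  expect_lt(sg[which(c05 < 0.01)[1]], sg[which(c15 < 0.01)[1]])
})

test_that("the default scheme counts 19 encodings and accepts custom full-rank sets", {
  sch <- encodingScheme()
  expect_equal(nEncodings(sch), 19L)
  expect_equal(nrow(schemeIndex(sch)), 19L)
  expect_true(is.na(schemeIndex(sch)$direction[1]))
  # a rank-deficient set is rejected (all six directions coplanar)
  bad <- matrix(c(1, 0, 0,
                  0, 1, 0,
                  1, 1, 0,
                  1, -1, 0,
                  2, 1, 0,
                  1, 2, 0), ncol = 3, byrow = TRUE)
  expect_error(encodingScheme(directions = bad), "rank")
  # any symmetric tensor is determined by the six direction variances
  D <- buildDirections()
  H <- quadraticDesign(D)
  set.seed(3)
  for (i in 1:5) {
    R <- randomPsdTensor(80)
    v6 <- c(R[1, 1], R[2, 2], R[3, 3], R[1, 2], R[1, 3], R[2, 3])
    expect_equal(as.numeric(solve(H, H %*% v6)), v6)
  }
})

test_that("schemes round-trip through YAML", {
  sch <- encodingScheme(vencs = c(0.4, 0.67, 2.0))
  p <- tempfile(fileext = ".yaml")
  writeEncodingScheme(sch, p)
  sch2 <- readEncodingScheme(p)
  expect_equal(directions(sch2), directions(sch))
  expect_equal(vencs(sch2), vencs(sch))
  expect_equal(nEncodings(sch2), nEncodings(sch))
})
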