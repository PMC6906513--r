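# Shared fixtures: random symmetric positive-definite tensors, tiny phantoms
# and stacks, built in code at test time.

randomPsdTensor <- function(scale = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(9), 3L)
  crossprod(A) * scale / 3
}

randomRotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3L)))
}

tinyPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateJetPhantom(dims = c(16L, 16L, 32L), seed = 7L)
    cache
  }
})

tinyStack <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- encodePhantom(tinyPhantom(), encodingScheme())
    cache
  }
})

relErr <- function(est, truth) {
  max(abs(est - truth)) / max(abs(truth))
}

nrmse <- function(est, truth) {
  sqrt(sum(Mod(est - truth)^2) / sum(Mod(truth)^2))
}

writeTestConfig <- function(path, dims = c(12L, 12L, 16L), extra = list()) {
  cfg <- modifyList(list(
    output = file.path(tempdir(), "turbmri-test-out"),
    seed = 5L,
    density = 1200,   # match the phantom fluid so estimates are in its units
    phantom = list(dims = as.integer(dims), spacing = 0.625)), extra)
  yaml::write_yaml(cfg, path)
  path
}
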