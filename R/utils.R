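# Internal numerical helpers: tensor component packing, fast symmetric 3x3
# eigenvalues, seed derivation and argument checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Deterministic derivation of per-stage seeds from one base seed; keeps every
# derived seed a valid 32-bit integer.
deriveSeed <- function(base, stage = 0L) {
  base <- as.numeric(base); stage <- as.numeric(stage)
  as.integer((base * 100003 + stage * 7919 + 12345) %% 2147483629)
}

# (xx, yy, zz, xy, xz, yz) <-> symmetric 3x3
rstVecToMat <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3L, 3L)
}

rstMatToVec <- function(R) {
  c(R[1, 1], R[2, 2], R[3, 3], R[1, 2], R[1, 3], R[2, 3])
}

# Eigenvalues of many symmetric 3x3 matrices at once, rows of an n x 6 matrix
# in (xx,yy,zz,xy,xz,yz) order. Returns n x 3 matrix, descending per row.
# Analytic trigonometric solution of the characteristic cubic.
symEigenvalues3 <- function(V) {
  V <- matrix(V, ncol = 6L)
  a11 <- V[, 1]; a22 <- V[, 2]; a33 <- V[, 3]
  a12 <- V[, 4]; a13 <- V[, 5]; a23 <- V[, 6]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  e1 <- q; e2 <- q; e3 <- q
  nz <- p > 0
  if (any(nz)) {
    pn <- p[nz]
    b11 <- (a11[nz] - q[nz]) / pn; b22 <- (a22[nz] - q[nz]) / pn
    b33 <- (a33[nz] - q[nz]) / pn
    b12 <- a12[nz] / pn; b13 <- a13[nz] / pn; b23 <- a23[nz] / pn
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1[nz] <- q[nz] + 2 * pn * cos(phi)
    e3[nz] <- q[nz] + 2 * pn * cos(phi + 2 * pi / 3)
    e2[nz] <- 3 * q[nz] - e1[nz] - e3[nz]
  }
  cbind(e1, e2, e3, deparse.level = 0)
}

# Flatten the spatial dims of a [nx,ny,nz,k] array into an (nVox x k) matrix
# restricted to masked voxels.
maskedComponents <- function(arr, mask) {
  k <- dim(arr)[4L]
  m <- matrix(arr, ncol = k)
  m[as.vector(mask), , drop = FALSE]
}

# Inverse of maskedComponents: scatter rows back into a zero array.
scatterComponents <- function(values, mask, k = ncol(values)) {
  arr <- array(0, c(dim(mask), k))
  m <- matrix(arr, ncol = k)
  m[as.vector(mask), ] <- values
  array(m, c(dim(mask), k))
}

# Vectorized parabolic refinement over rows of a cost matrix C (nVox x nGrid)
# with grid g. Returns list(argmin, min) with sub-grid argmin per row.
parabolicMinRows <- function(C, g) {
  idx <- max.col(-C, ties.method = "first")
  n <- length(g)
  i0 <- pmax(pmin(idx, n - 1L), 2L)
  rows <- seq_len(nrow(C))
  ym <- C[cbind(rows, i0 - 1L)]
  y0 <- C[cbind(rows, i0)]
  yp <- C[cbind(rows, i0 + 1L)]
  denom <- ym - 2 * y0 + yp
  h <- g[2] - g[1]
  delta <- ifelse(is.finite(denom) & denom > 0,
                  0.5 * h * (ym - yp) / denom, 0)
  delta[idx == 1L | idx == n] <- 0
  list(argmin = g[pmin(pmax(idx, 1L), n)] + delta, index = idx)
}
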