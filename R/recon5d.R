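# Cardiac/respiratory-binned Cartesian k-space: tiny-golden-angle sampling
# masks, view sharing across respiratory states, Casorati block extraction,
# singular-value thresholding and the locally low-rank reconstruction.

# Unitary, centered 3-d FFT pair (operator norm 1, so the proximal-gradient
# step size has a clean bound). K-space arrays are stored DC-centered: the
# zero frequency sits at index floor(n/2)+1 per dimension, matching the
# sampling-mask convention of goldenAngleMask().
rollDim <- function(x, shifts) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(a) {
    s <- shifts[a] %% d[a]
    if (s == 0) seq_len(d[a]) else c((d[a] - s + 1L):d[a], seq_len(d[a] - s))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

fftshift3 <- function(x) rollDim(x, floor(dim(x) / 2))
ifftshift3 <- function(x) rollDim(x, -floor(dim(x) / 2))

fft3u <- function(x) fftshift3(fft(x)) / sqrt(length(x))
ifft3u <- function(k) fft(ifftshift3(k), inverse = TRUE) / sqrt(length(k))

#' Tiny-golden-angle Cartesian sampling masks
#'
#' Orders the phase-encode (ky, kz) grid points along pseudo-spokes through
#' the k-space center whose angles advance by a tiny golden angle
#' (180 / (golden ratio + N - 1) degrees), and assigns them sequentially to
#' frames: frame 1 receives the first `linesPerFrame` distinct points, frame
#' 2 the next, and so on. The center point is added to every frame. The
#' construction is fully deterministic. Grid points never reached by a spoke
#' (possible for very full frames) are appended in center-out order so that
#' `linesPerFrame = prod(dims)` yields fully sampled frames.
#'
#' @param dims c(nky, nkz) phase-encode grid size.
#' @param linesPerFrame phase-encode points per frame, >= 1.
#' @param nFrames number of frames.
#' @param tinyN tiny-golden-angle index N (default 7, ~23.63 degrees).
#' @return logical array [nky, nkz, nFrames].
#' @export
goldenAngleMask <- function(dims, linesPerFrame, nFrames, tinyN = 7L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 2L, linesPerFrame >= 1L, nFrames >= 1L)
  total <- prod(dims)
  linesPerFrame <- min(as.integer(linesPerFrame), total)
  psi <- pi / ((1 + sqrt(5)) / 2 + tinyN - 1)
  cy <- floor(dims[1] / 2) + 1L; cz <- floor(dims[2] / 2) + 1L
  rmax <- sqrt(max(dims[1] - cy, cy - 1)^2 + max(dims[2] - cz, cz - 1)^2)
  radii <- seq(0, rmax, by = 0.5)
  # stream of grid points along successive spokes (center-out, both halves)
  nSpokes <- max(64L, 8L * ceiling(nFrames * linesPerFrame / max(1, rmax)))
  streamOf <- function(nsp) {
    ang <- (seq_len(nsp) - 1L) * psi
    pts <- lapply(ang, function(a) {
      y <- round(cy + c(rbind(radii, -radii)) * cos(a))
      z <- round(cz + c(rbind(radii, -radii)) * sin(a))
      ok <- y >= 1L & y <= dims[1] & z >= 1L & z <= dims[2]
      lin <- (y[ok] - 1L) + (z[ok] - 1L) * dims[1] + 1L
      lin[!duplicated(lin)]
    })
    unlist(pts, use.names = FALSE)
  }
  stream <- streamOf(nSpokes)
  mask <- array(FALSE, c(dims, nFrames))
  centerLin <- (cy - 1L) + (cz - 1L) * dims[1] + 1L
  # center-out fallback ordering for points a spoke never hits
  yy <- rep(seq_len(dims[1]), dims[2]); zz <- rep(seq_len(dims[2]), each = dims[1])
  fallback <- order((yy - cy)^2 + (zz - cz)^2, yy, zz)
  pos <- 1L
  for (f in seq_len(nFrames)) {
    got <- logical(total)
    got[centerLin] <- TRUE
    count <- 1L
    while (count < linesPerFrame) {
      if (pos > length(stream)) {
        extra <- fallback[!got[fallback]]
        take <- extra[seq_len(min(length(extra), linesPerFrame - count))]
        got[take] <- TRUE
        count <- count + length(take)
        break
      }
      p <- stream[pos]; pos <- pos + 1L
      if (!got[p]) { got[p] <- TRUE; count <- count + 1L }
    }
    mask[, , f][got] <- TRUE
  }
  mask
}

#' Per-frame acceleration factors
#'
#' Ratio of total phase-encode points to sampled points, per
#' (cardiac phase, respiratory state) frame.
#'
#' @param binned a [BinnedKSpace-class].
#' @return numeric matrix [nPhases, nStates].
#' @export
frameAcceleration <- function(binned) {
  stopifnot(is(binned, "BinnedKSpace"))
  dm <- dim(binned@mask)
  total <- prod(dm[1:2])
  matrix(total / pmax(apply(binned@mask, 3:4, sum), 1L), dm[3], dm[4])
}

#' View sharing across respiratory states
#'
#' Frames whose acceleration exceeds the cap borrow phase-encode points from
#' the same cardiac phase in neighboring respiratory states (nearest state
#' first, smaller state index breaking ties, center-out point order within a
#' donor) until the cap is met or all donors are exhausted. A frame's own
#' acquired points are never overwritten; borrowed points are flagged in the
#' `shared` mask.
#'
#' @param binned a [BinnedKSpace-class].
#' @param maxAcceleration acceleration cap (> 1), e.g. 35.
#' @return a [BinnedKSpace-class] with augmented mask/data and `shared`
#'   flags.
#' @export
viewShare <- function(binned, maxAcceleration) {
  stopifnot(is(binned, "BinnedKSpace"), maxAcceleration > 1)
  dm <- dim(binned@mask)
  nky <- dm[1]; nkz <- dm[2]; nHP <- dm[3]; nRS <- dm[4]
  total <- nky * nkz
  need <- ceiling(total / maxAcceleration)
  cy <- floor(nky / 2) + 1L; cz <- floor(nkz / 2) + 1L
  yy <- rep(seq_len(nky), nkz); zz <- rep(seq_len(nkz), each = nky)
  centerOut <- order((yy - cy)^2 + (zz - cz)^2, yy, zz)
  mask <- binned@mask; data <- binned@data; shared <- binned@shared
  for (hp in seq_len(nHP)) for (rs in seq_len(nRS)) {
    have <- sum(mask[, , hp, rs])
    if (have >= need) next
    donors <- setdiff(order(abs(seq_len(nRS) - rs), seq_len(nRS)), rs)
    for (dn in donors) {
      if (have >= need) break
      donorMask <- mask[, , hp, dn] & !shared[, , hp, dn]
      cand <- centerOut[donorMask[centerOut] & !mask[, , hp, rs][centerOut]]
      if (!length(cand)) next
      take <- cand[seq_len(min(length(cand), need - have))]
      m2 <- mask[, , hp, rs]; s2 <- shared[, , hp, rs]
      m2[take] <- TRUE; s2[take] <- TRUE
      mask[, , hp, rs] <- m2; shared[, , hp, rs] <- s2
      for (p in take) {
        py <- (p - 1L) %% nky + 1L; pz <- (p - 1L) %/% nky + 1L
        data[, py, pz, hp, rs] <- data[, py, pz, hp, dn]
      }
      have <- have + length(take)
    }
  }
  new("BinnedKSpace", data = data, mask = mask, shared = shared)
}

#' Casorati matrix of an image block
#'
#' Extracts a cubic block from every (cardiac phase, respiratory state) frame
#' of a dynamic series and vectorizes each into a column. Column order is
#' cardiac-major: the cardiac phase index varies fastest.
#'
#' @param series complex array [nx, ny, nz, nPhases, nStates].
#' @param origin block corner c(i, j, k) (1-based).
#' @param blockSize block edge lengths, scalar or length 3.
#' @return complex matrix (prod(blockSize) x nPhases*nStates).
#' @export
buildCasorati <- function(series, origin, blockSize) {
  d <- dim(series)
  stopifnot(length(d) == 5L)
  bs <- rep_len(as.integer(blockSize), 3L)
  origin <- as.integer(origin)
  if (any(origin < 1L) || any(origin + bs - 1L > d[1:3]))
    stop("block exceeds volume bounds")
  blk <- series[origin[1]:(origin[1] + bs[1] - 1L),
                origin[2]:(origin[2] + bs[2] - 1L),
                origin[3]:(origin[3] + bs[3] - 1L), , , drop = FALSE]
  matrix(blk, nrow = prod(bs), ncol = d[4] * d[5])
}

#' Singular-value soft-thresholding
#'
#' Proximal operator of tau times the nuclear norm: SVD with singular values
#' shrunk by `tau` (and floored at zero).
#'
#' @param M complex (or numeric) matrix.
#' @param tau threshold, >= 0.
#' @return matrix of the same shape.
#' @export
svtShrink <- function(M, tau) {
  assertScalar(tau, "tau", nonneg = TRUE)
  if (tau == 0) return(M)
  s <- svd(M)
  keep <- pmax(s$d - tau, 0)
  nz <- keep > 0
  if (!any(nz)) return(M * 0)
  s$u[, nz, drop = FALSE] %*% (keep[nz] * Conj(t(s$v[, nz, drop = FALSE])))
}

# Non-overlapping block tiling (boundary blocks truncated) with an optional
# cyclic shift; returns list of origin/size pairs on the shifted grid.
blockTiling <- function(dims, blockSize, shift = c(0L, 0L, 0L)) {
  starts <- lapply(1:3, function(a) {
    s <- seq(1L - (shift[a] %% blockSize), dims[a], by = blockSize)
    s[s + blockSize - 1L >= 1L]
  })
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  lapply(seq_len(nrow(grid)), function(i) {
    o <- pmax(c(grid$x[i], grid$y[i], grid$z[i]), 1L)
    e <- pmin(c(grid$x[i], grid$y[i], grid$z[i]) + blockSize - 1L, dims)
    if (any(e < o)) NULL else list(origin = o, size = e - o + 1L)
  })
}

# Apply SVT to every block of the series in place; returns the series and the
# summed nuclear norm of the (un-thresholded) blocks.
blockSvtPass <- function(series, blockSize, tau, shift = c(0L, 0L, 0L)) {
  d <- dim(series)
  nF <- d[4] * d[5]
  nuc <- 0
  for (b in blockTiling(d[1:3], blockSize, shift)) {
    if (is.null(b)) next
    ii <- b$origin[1]:(b$origin[1] + b$size[1] - 1L)
    jj <- b$origin[2]:(b$origin[2] + b$size[2] - 1L)
    kk <- b$origin[3]:(b$origin[3] + b$size[3] - 1L)
    M <- matrix(series[ii, jj, kk, , , drop = FALSE], ncol = nF)
    s <- svd(M)
    nuc <- nuc + sum(s$d)
    if (tau > 0) {
      keep <- pmax(s$d - tau, 0)
      M2 <- s$u %*% (keep * Conj(t(s$v)))
      series[ii, jj, kk, , ] <- array(M2, c(b$size, d[4], d[5]))
    }
  }
  list(series = series, nuclear = nuc)
}

# Total nuclear norm over the canonical (unshifted) tiling.
blockNuclearNorm <- function(series, blockSize) {
  blockSvtPass(series, blockSize, 0)$nuclear
}

# Forward operator: coil-weighted unitary FFT per frame, then undersampling.
applyEncoding <- function(x, mask, coil) {
  d <- dim(x)
  out <- array(0 + 0i, d)
  for (hp in seq_len(d[4])) for (rs in seq_len(d[5])) {
    k <- fft3u(x[, , , hp, rs] * coil)
    k <- sweep(k, 2:3, as.numeric(mask[, , hp, rs]), "*")
    out[, , , hp, rs] <- k
  }
  out
}

# Adjoint: masked inverse FFT per frame, conjugate coil weighting.
applyAdjoint <- function(k, mask, coil) {
  d <- dim(k)
  out <- array(0 + 0i, d)
  for (hp in seq_len(d[4])) for (rs in seq_len(d[5])) {
    km <- sweep(k[, , , hp, rs], 2:3, as.numeric(mask[, , hp, rs]), "*")
    out[, , , hp, rs] <- Conj(coil) * ifft3u(km)
  }
  out
}

#' Locally low-rank reconstruction of binned k-space
#'
#' Iterative minimizer of
#' \deqn{\| \Omega \mathcal{F} \mathcal{C}(S) - d \|_2^2 +
#'       \lambda \sum_b \| \mathcal{R}_b(S) \|_*}
#' where the operators R_b extract cubic image blocks across all cardiac
#' phases and respiratory states and reshape them into Casorati matrices
#' whose nuclear norms are penalized. The solver is proximal gradient
#' descent (step 1/2 for the squared-norm data term with unitary FFT and
#' normalized coils, so the objective is monotone non-increasing), with the
#' proximal step realized by per-block singular-value thresholding.
#' FISTA acceleration and seeded cycle spinning of the block grid are
#' available but off by default because both break strict per-iteration
#' objective monotonicity.
#'
#' The k-space data are internally normalized so the zero-filled
#' reconstruction has unit maximum magnitude; `lambda` refers to that scale.
#' With `lambda = 0` and full sampling the zero-filled (inverse FFT)
#' solution is already optimal and is returned unchanged.
#'
#' @param binned a [BinnedKSpace-class].
#' @param coil complex coil-sensitivity volume [nx, ny, nz] with magnitudes
#'   <= 1 (default: uniform single coil).
#' @param cfg an [LlrConfig-class].
#' @param objectiveEvery compute the objective every this many iterations
#'   (1 = every iteration, the default; 0 = only at the end, which roughly
#'   halves the per-iteration cost on large problems).
#' @return list with `image` (complex array [nx,ny,nz,nPhases,nStates], on
#'   the original data scale), `objective` (values at the tracked
#'   iterations, normalized scale), `objectiveIter` (their iteration
#'   numbers), `iterations`, and `converged` (FALSE triggers a warning and
#'   returns the last iterate).
#' @export
llrReconstruct <- function(binned, coil = NULL, cfg = llrConfig(),
                           objectiveEvery = 1L) {
  stopifnot(is(binned, "BinnedKSpace"), is(cfg, "LlrConfig"))
  d <- dim(binned@data)
  if (is.null(coil)) coil <- array(1 + 0i, d[1:3])
  if (max(Mod(coil)) > 1 + 1e-9) stop("coil map must be normalized (<= 1)")
  x <- applyAdjoint(binned@data, binned@mask, coil)   # zero-filled recon
  scale <- max(Mod(x))
  if (scale == 0) scale <- 1
  dat <- binned@data / scale
  x <- x / scale
  step <- 0.5
  # geometric continuation from lambdaStart down to lambda (reached about
  # 60% of the way through the iteration budget)
  lamSeq <- if (cfg@lambdaStart > cfg@lambda && cfg@lambda > 0) {
    decay <- (cfg@lambda / cfg@lambdaStart)^(1 / max(1, 0.6 * cfg@maxIter))
    pmax(cfg@lambda, cfg@lambdaStart * decay^(seq_len(cfg@maxIter) - 1L))
  } else rep(cfg@lambda, cfg@maxIter)
  shifts <- matrix(0L, cfg@maxIter, 3L)
  if (cfg@cycleSpin) {
    set.seed(cfg@seed)
    shifts <- matrix(sample.int(cfg@blockSize, 3L * cfg@maxIter,
                                replace = TRUE) - 1L, ncol = 3L)
  }
  objAt <- function(z) {
    r <- applyEncoding(z, binned@mask, coil) - dat
    sum(Mod(r)^2) + cfg@lambda * blockNuclearNorm(z, cfg@blockSize)
  }
  objective <- numeric(0)
  objectiveIter <- integer(0)
  tPrev <- 1; xPrev <- x
  stopped <- FALSE
  for (it in seq_len(cfg@maxIter)) {
    y <- if (cfg@accelerate && it > 1L) {
      tCur <- (1 + sqrt(1 + 4 * tPrev^2)) / 2
      z <- x + ((tPrev - 1) / tCur) * (x - xPrev)
      tPrev <- tCur
      z
    } else x
    res <- applyEncoding(y, binned@mask, coil) - dat
    grad <- 2 * applyAdjoint(res, binned@mask, coil)
    xPrev <- x
    x <- y - step * grad
    if (lamSeq[it] > 0)
      x <- blockSvtPass(x, cfg@blockSize, lamSeq[it] * step,
                        shifts[it, ])$series
    if (objectiveEvery > 0L && it %% objectiveEvery == 0L) {
      obj <- objAt(x)
      objective <- c(objective, obj)
      objectiveIter <- c(objectiveIter, it)
      n <- length(objective)
      if (n > 1L && lamSeq[it] == cfg@lambda &&
          abs(objective[n - 1L] - obj) <=
          cfg@tol * max(abs(objective[n - 1L]), 1e-12)) {
        stopped <- TRUE
        break
      }
    }
  }
  if (objectiveEvery == 0L || length(objective) == 0L ||
      objectiveIter[length(objectiveIter)] < it) {
    objective <- c(objective, objAt(x))
    objectiveIter <- c(objectiveIter, it)
  }
  converged <- stopped || it < cfg@maxIter
  if (!converged && cfg@tol > 0 && objectiveEvery == 1L)
    warning("llrReconstruct: objective still changing at maxIter; ",
            "returning the final iterate")
  list(image = x * scale, objective = objective,
       objectiveIter = objectiveIter, iterations = it,
       converged = converged)
}

#' Synthetic low-rank dynamic series and its binned k-space
#'
#' Builds a spatio-temporal phantom of exact rank `rank`: random smooth
#' spatial modes (sums of Gaussian blobs) weighted by smooth temporal
#' profiles over cardiac phases and respiratory states. Used to exercise the
#' locally low-rank reconstruction with a known ground truth.
#'
#' @param dims spatial grid c(nx, ny, nz).
#' @param nPhases,nStates cardiac/respiratory bin counts.
#' @param rank number of spatio-temporal modes.
#' @param seed integer seed.
#' @return list with `series` (complex array [nx,ny,nz,nPhases,nStates]).
#' @export
dynamicRankPhantom <- function(dims = c(32L, 32L, 32L), nPhases = 8L,
                               nStates = 4L, rank = 2L, seed = 1L) {
  dims <- as.integer(dims)
  set.seed(deriveSeed(seed, 11L))
  xs <- seq(-1, 1, length.out = dims[1])
  ys <- seq(-1, 1, length.out = dims[2])
  zs <- seq(-1, 1, length.out = dims[3])
  series <- array(0 + 0i, c(dims, nPhases, nStates))
  for (m in seq_len(rank)) {
    mode <- array(0, dims)
    for (b in 1:3) {
      c0 <- runif(3, -0.5, 0.5); w <- runif(1, 0.15, 0.4)
      g <- exp(-outer(outer((xs - c0[1])^2, (ys - c0[2])^2, "+"),
                      (zs - c0[3])^2, "+") / (2 * w^2))
      mode <- mode + runif(1, 0.5, 1) * g
    }
    phHP <- runif(1, 0, 2 * pi); phRS <- runif(1, 0, 2 * pi)
    th <- 2 * pi * (seq_len(nPhases) - 1) / nPhases
    ps <- 2 * pi * (seq_len(nStates) - 1) / nStates
    # distinct cardiac harmonic per mode so the temporal signatures are
    # well separated (mode 1 keeps a DC component, higher modes oscillate)
    wHP <- if (m == 1L) 1 + 0.5 * cos(th + phHP) else
      cos((m - 1L) * th + phHP)
    wRS <- if (m == 1L) 1 + 0.3 * cos(ps + phRS) else
      1 + 0.4 * sin(ps + phRS)
    tw <- outer(wHP, wRS)
    for (hp in seq_len(nPhases)) for (rs in seq_len(nStates))
      series[, , , hp, rs] <- series[, , , hp, rs] + mode * tw[hp, rs]
  }
  list(series = series)
}

#' Binned k-space from a dynamic image series
#'
#' Applies the unitary FFT per frame and the per-frame sampling masks,
#' producing the [BinnedKSpace-class] a reconstruction would see.
#'
#' @param series complex array [nx, ny, nz, nPhases, nStates].
#' @param mask logical array [nky, nkz, nPhases, nStates] (or
#'   [nky, nkz, nFrames] which is reshaped cardiac-major).
#' @param coil optional coil map [nx, ny, nz].
#' @return a [BinnedKSpace-class].
#' @export
kspaceFromSeries <- function(series, mask, coil = NULL) {
  d <- dim(series)
  if (length(dim(mask)) == 3L) dim(mask) <- c(dim(mask)[1:2], d[4], d[5])
  if (is.null(coil)) coil <- array(1 + 0i, d[1:3])
  binnedKSpace(applyEncoding(series, mask, coil), mask)
}
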