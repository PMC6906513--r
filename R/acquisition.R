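# Acquisition simulation: voxel-wise forward encoding of a phantom, k-space
# window downsampling to coarser voxel sizes, complex noise at a target SNR,
# and the Monte-Carlo accuracy/precision experiment driver.

#' Encode a phantom with a multi-VENC scheme
#'
#' Applies the tensor forward model voxel-wise for every encoding of the
#' scheme: magnitude attenuation from the local RST, phase from the local
#' mean velocity. The reference (kv = 0) volume is `s0` inside the lumen and
#' 0 outside, as are all encoded volumes.
#'
#' @param field a [PhantomField-class].
#' @param scheme an [EncodingScheme-class] (must include the reference).
#' @param s0 reference signal level.
#' @return an [EncodedImageStack-class] (noiseless, `snr = Inf`).
#' @export
encodePhantom <- function(field, scheme, s0 = 1) {
  stopifnot(is(field, "PhantomField"), is(scheme, "EncodingScheme"))
  if (!scheme@includesReference)
    stop("the estimation chain requires the reference (kv = 0) measurement")
  idx <- schemeIndex(scheme)
  dims <- dim(field@mask)
  mask <- field@mask
  V <- maskedComponents(field@velocity, mask)
  R6 <- maskedComponents(field@rst, mask)
  dirs <- directions(scheme)
  vols <- array(0 + 0i, c(dims, nrow(idx)))
  flat <- matrix(vols, ncol = nrow(idx))
  mVec <- as.vector(mask)
  for (j in seq_len(nrow(idx))) {
    if (is.na(idx$direction[j])) {
      sig <- rep(s0 + 0i, nrow(V))
    } else {
      kv <- computeKv(idx$venc[j]) * dirs[idx$direction[j], ]
      sig <- forwardSignalTensorMany(s0, V, R6, field@fluidDensity, kv)
    }
    col <- flat[, j]
    col[mVec] <- sig
    flat[, j] <- col
  }
  new("EncodedImageStack", volumes = array(flat, c(dims, nrow(idx))),
      index = idx, scheme = scheme, spacing = field@spacing, mask = mask,
      snr = Inf, noiseSd = 0, seed = NA_integer_)
}

# Low-frequency (unshifted-spectrum) index set retaining m of n samples.
lowFreqIndex <- function(n, m) {
  hi <- ceiling(m / 2); lo <- m - hi
  c(seq_len(hi), if (lo > 0) seq(n - lo + 1L, n))
}

# Separable window weights over the retained band (centered frequencies).
bandWindow <- function(m, window) {
  if (window == "rect") return(rep(1, m))
  hi <- ceiling(m / 2); lo <- m - hi
  f <- c(seq(0, hi - 1L), if (lo > 0) seq(-lo, -1L))   # unshifted order
  0.5 * (1 + cos(2 * pi * f / m))                       # Hann over the band
}

# Downsample one complex volume by cropping central k-space; preserves the
# image-domain mean (DC) exactly.
downsampleVolume <- function(vol, factor, window = "rect") {
  d <- dim(vol)
  m <- d %/% factor
  K <- fft(vol)
  ix <- lowFreqIndex(d[1], m[1]); iy <- lowFreqIndex(d[2], m[2])
  iz <- lowFreqIndex(d[3], m[3])
  Kc <- K[ix, iy, iz, drop = FALSE]
  if (window != "rect") {
    wx <- bandWindow(m[1], window); wy <- bandWindow(m[2], window)
    wz <- bandWindow(m[3], window)
    Kc <- Kc * (wx %o% wy %o% wz)
  }
  fft(Kc, inverse = TRUE) / prod(d)
}

#' Downsample an encoded stack via k-space windowing
#'
#' Emulates acquisition at a coarser voxel size: each volume is Fourier
#' transformed, only the central phase-encode region (bandwidth inversely
#' proportional to the downsampling factor) is retained — optionally shaped
#' by a Hann window — and the inverse transform is taken on the reduced
#' grid. Factor 1 returns the stack unchanged. The lumen mask is downsampled
#' by the same operator and thresholded at 0.5.
#'
#' @param stack an [EncodedImageStack-class].
#' @param factor integer >= 1; must divide all grid dimensions.
#' @param window `"rect"` (ideal low-pass, default) or `"hann"`.
#' @return the downsampled [EncodedImageStack-class] (spacing scaled by
#'   `factor`).
#' @export
windowDownsample <- function(stack, factor, window = c("rect", "hann")) {
  stopifnot(is(stack, "EncodedImageStack"))
  window <- match.arg(window)
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(stack)
  d <- dim(stack@volumes)[1:3]
  if (any(d %% factor != 0L))
    stop("factor must divide all grid dimensions")
  m <- d %/% factor
  nEnc <- dim(stack@volumes)[4L]
  vols <- array(0 + 0i, c(m, nEnc))
  for (j in seq_len(nEnc))
    vols[, , , j] <- downsampleVolume(stack@volumes[, , , j], factor, window)
  maskLow <- Re(downsampleVolume(array(as.numeric(stack@mask), d),
                                 factor, window))
  new("EncodedImageStack", volumes = vols, index = stack@index,
      scheme = stack@scheme, spacing = stack@spacing * factor,
      mask = array(maskLow > 0.5, m), snr = stack@snr,
      noiseSd = stack@noiseSd, seed = stack@seed)
}

#' Add complex Gaussian noise at a target SNR
#'
#' Adds i.i.d. circular complex Gaussian noise to every volume of the stack,
#' with the per-channel standard deviation chosen so that
#' `snrDb(signal, sd)` equals the target, where the signal level is the mean
#' magnitude over the analysis mask averaged over all velocity encodings.
#' An infinite target SNR returns the stack unchanged.
#'
#' @param stack an [EncodedImageStack-class].
#' @param targetSnrDb target SNR, dB (may be `Inf`).
#' @param mask analysis mask for the signal level (default: stack mask).
#' @param seed integer seed for the noise draw.
#' @return the noisy [EncodedImageStack-class] with `snr`/`noiseSd`/`seed`
#'   recorded.
#' @export
addNoise <- function(stack, targetSnrDb, mask = NULL, seed = 1L) {
  stopifnot(is(stack, "EncodedImageStack"))
  if (is.infinite(targetSnrDb)) return(stack)
  assertScalar(targetSnrDb, "targetSnrDb")
  if (is.null(mask)) mask <- stack@mask
  if (!any(mask)) stop("analysis mask is empty")
  level <- mean(Mod(maskedComponents(stack@volumes, mask)))
  sd0 <- noiseSdForSnr(level, targetSnrDb)
  set.seed(deriveSeed(seed, 3L))
  n <- length(stack@volumes)
  noisy <- stack@volumes +
    array(complex(real = rnorm(n, 0, sd0), imaginary = rnorm(n, 0, sd0)),
          dim(stack@volumes))
  new("EncodedImageStack", volumes = noisy, index = stack@index,
      scheme = stack@scheme, spacing = stack@spacing, mask = stack@mask,
      snr = targetSnrDb, noiseSd = sd0, seed = as.integer(seed))
}

#' Monte-Carlo accuracy/precision experiment over SNR and voxel size
#'
#' For every combination of SNR, downsampling factor and repetition: encode
#' the phantom, window-downsample, add seeded noise, run the estimation
#' chain, median-filter the tensor components, compute TKE and MPTSS maps and
#' record the masked distribution mean and standard deviation. The output is
#' one long-format row per (snr, factor, rep) cell; [summarizeExperiment()]
#' aggregates mean +/- sd over the repetitions.
#'
#' @param field a [PhantomField-class].
#' @param scheme an [EncodingScheme-class].
#' @param snrList SNR values, dB (`Inf` allowed for noiseless).
#' @param factorList integer downsampling factors.
#' @param nReps repetitions per cell (>= 2 for spread estimates; 1 allowed
#'   for noiseless reference runs).
#' @param seed base seed; all per-rep noise seeds derive from it.
#' @param medianSize median-filter size (odd; 1 disables).
#' @param method estimation path, see [estimateStack()].
#' @param ... further arguments to [estimateStack()].
#' @return data.frame with columns snr, factor, rep, tkeMean, tkeSd,
#'   mptssMean, mptssSd, nVoxels.
#' @export
accuracyPrecisionExperiment <- function(field, scheme, snrList = c(40, 30, 20),
                                        factorList = 1L, nReps = 10L,
                                        seed = 1L, medianSize = 3L,
                                        method = "bayes", ...) {
  stopifnot(is(field, "PhantomField"), nReps >= 1L)
  native <- encodePhantom(field, scheme)
  rho <- field@fluidDensity
  rows <- list()
  for (fi in seq_along(factorList)) {
    f <- factorList[fi]
    stackF <- windowDownsample(native, f)
    for (si in seq_along(snrList)) {
      for (rep in seq_len(nReps)) {
        repSeed <- deriveSeed(seed, fi * 1000000L + si * 10000L + rep)
        noisy <- addNoise(stackF, snrList[si], seed = repSeed)
        est <- estimateStack(noisy, rho = rho, method = method, ...)
        rstF <- medianFilterRst(est$rst, est$mask, size = medianSize)
        maps <- turbulenceMaps(rstF, est$mask)
        tkeVals <- maps$tke[maps$mask]
        mpVals <- maps$mptss[maps$mask]
        rows[[length(rows) + 1L]] <- data.frame(
          snr = snrList[si], factor = f, rep = rep,
          tkeMean = mean(tkeVals), tkeSd = sd(tkeVals),
          mptssMean = mean(mpVals), mptssSd = sd(mpVals),
          nVoxels = sum(maps$mask))
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate an accuracy/precision experiment over repetitions
#'
#' @param tbl output of [accuracyPrecisionExperiment()].
#' @return data.frame with one row per (snr, factor) and mean/sd over reps of
#'   each recorded metric.
#' @export
summarizeExperiment <- function(tbl) {
  key <- interaction(tbl$snr, tbl$factor, drop = TRUE)
  agg <- lapply(split(tbl, key), function(g) data.frame(
    snr = g$snr[1], factor = g$factor[1], nReps = nrow(g),
    tkeMean = mean(g$tkeMean), tkeMeanSd = sd(g$tkeMean),
    tkeSd = mean(g$tkeSd), tkeSdSd = sd(g$tkeSd),
    mptssMean = mean(g$mptssMean), mptssMeanSd = sd(g$mptssMean),
    mptssSd = mean(g$mptssSd), mptssSdSd = sd(g$mptssSd)))
  out <- do.call(rbind, agg)
  out[order(out$factor, -out$snr), , drop = FALSE]
}
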