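# Forward MR signal model for phase-contrast velocity encoding with Gaussian
# intra-voxel velocity distributions, and SNR utilities.

#' One-dimensional phase-contrast signal model
#'
#' For a Gaussian intra-voxel velocity distribution with mean `vMean` and
#' standard deviation `sigma` along the encoding axis, the complex signal
#' after a bipolar encoding with first moment `kv` is
#' \deqn{S(k_v) = S_0 \, e^{-\sigma^2 k_v^2 / 2} \, e^{-i k_v \bar v}.}
#' Velocity fluctuations attenuate the magnitude; the mean velocity appears
#' as a phase (negative sign convention, fixed package-wide).
#'
#' All arguments are recycled to a common length, so whole volumes can be
#' evaluated in one call.
#'
#' @param s0 complex (or numeric) fully flow-compensated signal.
#' @param vMean mean velocity along the encoding axis, m/s.
#' @param sigma intra-voxel standard deviation (IVSD), m/s, >= 0.
#' @param kv first gradient moment, rad s/m (kv = pi / VENC).
#' @return complex signal, same length as the longest input.
#' @examples
#' forwardSignal1D(1, 0, 1, 1)          # magnitude exp(-1/2)
#' Arg(forwardSignal1D(1, 0.5, 0, pi / 0.5))  # phase -pi at v = VENC
#' @export
forwardSignal1D <- function(s0, vMean, sigma, kv) {
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("sigma must be finite and >= 0")
  s0 * exp(-sigma^2 * kv^2 / 2) * exp(-1i * kv * vMean)
}

#' Tensor phase-contrast signal model
#'
#' Complex signal of a voxel with mean velocity \eqn{\bar v} and Reynolds
#' stress tensor R (Pa) under an encoding with first-moment vector
#' \eqn{k_v}:
#' \deqn{|S| = |S_0| \exp(-k_v^\top R k_v / (2\rho)), \quad
#'       \arg S = \arg S_0 - k_v \cdot \bar v.}
#' The magnitude attenuation generalizes the one-dimensional Gaussian model to
#' anisotropic, correlated velocity fluctuations; the phase carries the mean
#' velocity projected onto the encoding direction.
#'
#' @param s0 complex reference signal.
#' @param state a [VoxelFlowState-class].
#' @param enc an [EncodingVector-class].
#' @return complex signal.
#' @examples
#' st <- voxelFlowState(c(1, 0, 0), diag(3) * 106, 1060)
#' forwardSignalTensor(1, st, encodingVector(c(0, 0, 1), 1.5))
#' @export
forwardSignalTensor <- function(s0, state, enc) {
  stopifnot(is(state, "VoxelFlowState"), is(enc, "EncodingVector"))
  validObject(state)
  kv <- kvVector(enc)
  att <- exp(-as.numeric(t(kv) %*% state@rst %*% kv) /
               (2 * state@fluidDensity))
  s0 * att * exp(-1i * sum(kv * state@meanVelocity))
}

# Vectorized tensor forward model over many voxels: V (n x 3) mean velocities,
# R (n x 6) tensors in Pa, one encoding (kv vector). Used by encodePhantom().
forwardSignalTensorMany <- function(s0, V, R6, rho, kv) {
  d <- kv
  # kv' R kv with R in (xx,yy,zz,xy,xz,yz) packing
  quad <- R6[, 1] * d[1]^2 + R6[, 2] * d[2]^2 + R6[, 3] * d[3]^2 +
    2 * (R6[, 4] * d[1] * d[2] + R6[, 5] * d[1] * d[3] +
           R6[, 6] * d[2] * d[3])
  phase <- V[, 1] * d[1] + V[, 2] * d[2] + V[, 3] * d[3]
  s0 * exp(-quad / (2 * rho)) * exp(-1i * phase)
}

#' Signal-to-noise ratio in decibel
#'
#' \deqn{\mathrm{SNR} = 20 \log_{10}(\mathrm{signal} / \mathrm{sd(noise)})}
#' with `noiseSd` the per-channel (real/imaginary) standard deviation of the
#' complex Gaussian noise.
#'
#' @param signalLevel mean signal magnitude over the analysis mask and all
#'   velocity encodings, > 0.
#' @param noiseSd per-channel noise standard deviation, > 0.
#' @return SNR in dB.
#' @examples
#' snrDb(31.6228, 1)  # 30 dB
#' @export
snrDb <- function(signalLevel, noiseSd) {
  assertScalar(signalLevel, "signalLevel", positive = TRUE)
  assertScalar(noiseSd, "noiseSd", positive = TRUE)
  20 * log10(signalLevel / noiseSd)
}

#' Noise standard deviation for a target SNR
#'
#' Inverse of [snrDb()]: the per-channel noise standard deviation that yields
#' the requested SNR for a given signal level.
#'
#' @param signalLevel mean signal magnitude, > 0.
#' @param targetSnrDb target SNR, dB.
#' @return per-channel noise standard deviation.
#' @export
noiseSdForSnr <- function(signalLevel, targetSnrDb) {
  assertScalar(signalLevel, "signalLevel", positive = TRUE)
  assertScalar(targetSnrDb, "targetSnrDb")
  signalLevel / 10^(targetSnrDb / 20)
}

#' Draw circular complex Gaussian noise
#'
#' i.i.d. complex noise with independent real and imaginary parts of equal
#' standard deviation `sd` (the per-channel convention used throughout).
#'
#' @param n number of samples.
#' @param sd per-channel standard deviation.
#' @param seed optional integer seed.
#' @return complex vector of length `n`.
#' @export
complexNoise <- function(n, sd, seed = NULL) {
  assertScalar(sd, "sd", nonneg = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  complex(real = rnorm(n, 0, sd), imaginary = rnorm(n, 0, sd))
}
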