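# Synthetic ground-truth generator: an axisymmetric stenotic-jet flow field
# with a turbulent shear layer, on a fine isotropic grid. The phantom stands
# in for an optical reference measurement: it reproduces summary properties
# (voxel size, stenosis degree, peak velocity, peak IVSD, fluid density) with
# a fast analytic model, not a fluid-dynamics solve.

#' Generate a stenotic-jet flow phantom
#'
#' Builds a cylindrical vessel along z with a smooth area stenosis, a
#' post-stenotic jet (smooth top-hat axial profile with a shear annulus) and
#' a Reynolds stress field whose intensity peaks in the shear layer. The RST
#' is anisotropic with its principal axis along the local jet direction
#' (slightly tilted towards radial in the shear layer, which creates
#' covariances) and is positive semidefinite everywhere. A seeded band-limited
#' random modulation adds smooth spatial irregularity; the field is
#' bit-reproducible for identical seed and parameters.
#'
#' The IVSD scalarization used for targets and histograms is the
#' direction-averaged \eqn{\sqrt{\mathrm{tr}(R)/(3\rho)}}; the field is
#' normalized so its maximum equals `peakIvsd` exactly, hence scaling
#' `peakIvsd` by a factor scales the RST quadratically.
#'
#' @param dims grid size c(nx, ny, nz).
#' @param spacing isotropic voxel size, mm (default 0.625).
#' @param stenosis area-reduction fraction of the stenosis in [0, 1) —
#'   default 0.64.
#' @param peakVelocity peak jet velocity, m/s.
#' @param peakIvsd peak IVSD, m/s (patient-like ~0.8, healthy-like ~0.3;
#'   must be <= 1.2).
#' @param vesselRadius unstenosed lumen radius, mm; default 40% of the
#'   smaller in-plane field of view.
#' @param fluidDensity kg/m^3 (default 1200, a blood-mimicking fluid).
#' @param anisotropy ratio of the axial to transverse fluctuation variance
#'   (>= 1).
#' @param perturbation relative amplitude of the seeded smooth random
#'   modulation of velocity and IVSD.
#' @param seed integer seed.
#' @return A [PhantomField-class].
#' @examples
#' ph <- generateJetPhantom(dims = c(16, 16, 32), seed = 7)
#' max(ivsdVolume(ph))  # == peakIvsd
#' @export
generateJetPhantom <- function(dims = c(32L, 32L, 64L), spacing = 0.625,
                               stenosis = 0.64, peakVelocity = 2.0,
                               peakIvsd = 0.8, vesselRadius = NULL,
                               fluidDensity = 1200, anisotropy = 2,
                               perturbation = 0.05, seed = 1L) {
  if (stenosis < 0 || stenosis >= 1)
    stop("stenosis must be in [0, 1): full occlusion is not a flow phantom")
  assertScalar(spacing, "spacing", positive = TRUE)
  if (peakIvsd < 0 || peakIvsd > 1.2)
    stop("peakIvsd must lie in [0, 1.2] m/s")
  if (anisotropy < 1) stop("anisotropy must be >= 1")
  dims <- as.integer(dims)
  fovXY <- dims[1:2] * spacing
  if (is.null(vesselRadius)) vesselRadius <- 0.4 * min(fovXY)
  R0 <- vesselRadius
  # voxel-center coordinates, mm (0-based voxel i spans [i, i+1)*spacing)
  xs <- (seq_len(dims[1]) - 0.5) * spacing - fovXY[1] / 2
  ys <- (seq_len(dims[2]) - 0.5) * spacing - fovXY[2] / 2
  zs <- (seq_len(dims[3]) - 0.5) * spacing
  Lz <- dims[3] * spacing
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)
  r <- sqrt(X^2 + Y^2)

  radiusFactor <- sqrt(1 - stenosis)      # area stenosis -> radius scaling
  z0 <- 0.3 * Lz                          # throat position
  wz <- 0.08 * Lz                         # axial extent of the constriction
  Rz <- R0 * (1 - (1 - radiusFactor) * exp(-((Z - z0)^2) / (2 * wz^2)))
  mask <- r <= Rz

  # axial mean velocity: bulk flow scaled by the area ratio, with a smooth
  # top-hat jet profile whose core tracks the local radius downstream
  U0 <- peakVelocity * radiusFactor^2     # upstream bulk velocity
  rj <- radiusFactor * R0 * (1 + 0.15 * pmax(Z - z0, 0) / R0)  # jet core
  # the mean-velocity interface of the jet is thin, while the turbulent
  # mixing annulus around it is broad and spreads downstream — the scale
  # separation typical of post-stenotic shear layers
  wVel <- 0.18 * radiusFactor * R0 * (1 + 0.2 * pmax(Z - z0, 0) / R0)
  wShear <- 0.45 * radiusFactor * R0 * (1 + 0.35 * pmax(Z - z0, 0) / R0)
  rise <- 1 / (1 + exp(-(Z - (z0 - 2 * wz)) / (0.3 * wz)))
  decay <- exp(-pmax(Z - z0, 0) / (0.6 * Lz))
  Vc <- U0 + (peakVelocity - U0) * rise * decay
  prof <- 0.5 * (1 - tanh((r - rj) / wVel))
  upstream <- 1 - rise
  profUp <- pmax(1 - (r / pmax(Rz, 1e-9))^2, 0)   # parabolic upstream
  vz <- Vc * (prof * rise + profUp * upstream)

  # IVSD field: shear annulus downstream of the throat
  zPeak <- z0 + 1.5 * R0
  hz <- exp(-((Z - zPeak)^2) / (2 * (0.25 * Lz)^2)) *
    (1 / (1 + exp(-(Z - z0) / (0.5 * wz))))
  # wall taper: turbulence decays towards the lumen boundary
  wallTaper <- pmax(1 - (r / pmax(Rz, 1e-9))^3, 0)
  sigma <- (exp(-((r - rj)^2) / (2 * wShear^2)) + 0.03) * hz * wallTaper

  # seeded smooth random modulation (few low-frequency cosine modes)
  set.seed(deriveSeed(seed, 1L))
  nModes <- 4L
  kx <- runif(nModes, 0.5, 1.5) * 2 * pi / fovXY[1]
  ky <- runif(nModes, 0.5, 1.5) * 2 * pi / fovXY[2]
  kz <- runif(nModes, 0.5, 2.0) * 2 * pi / Lz
  phs <- runif(nModes, 0, 2 * pi)
  amp <- runif(nModes, 0.5, 1)
  mod <- array(0, dims)
  for (m in seq_len(nModes))
    mod <- mod + amp[m] * cos(kx[m] * X + ky[m] * Y + kz[m] * Z + phs[m])
  mod <- mod / max(abs(mod))
  # fine-scale component (wavelengths of a few mm): the phase-averaged flow
  # of a turbulent jet is not smooth below the annulus scale
  nFine <- 6L
  fineField <- function() {
    ff <- matrix(runif(3L * nFine, 0.35, 0.70), nFine, 3L)  # cycles/mm
    fphs <- runif(nFine, 0, 2 * pi)
    famp <- runif(nFine, 0.5, 1)
    fine <- array(0, dims)
    for (m in seq_len(nFine))
      fine <- fine + famp[m] *
        cos(2 * pi * (ff[m, 1] * X + ff[m, 2] * Y + ff[m, 3] * Z) + fphs[m])
    fine / max(abs(fine))
  }
  fineZ <- fineField(); fineX <- fineField(); fineY <- fineField()
  jetRegion <- prof * rise          # confine roughness to the jet
  rough <- perturbation * peakVelocity * jetRegion * wallTaper
  vz <- vz * (1 + perturbation * mod) + 3.0 * rough * fineZ
  sigma <- sigma * (1 + perturbation * mod + 2 * perturbation * fineZ)

  sigma[!mask] <- 0
  vz[!mask] <- 0
  # exact peak normalization (quadratic RST scaling in peakIvsd)
  sigma <- if (peakIvsd > 0) sigma * (peakIvsd / max(sigma)) else sigma * 0

  # in-plane velocity: smooth secondary flow plus fine-scale roughness
  # (transverse weaker than axial)
  vx <- 0.05 * peakVelocity * mod * pmax(1 - (r / pmax(Rz, 1e-9))^2, 0) +
    1.8 * rough * fineX
  vy <- -0.04 * peakVelocity * mod * pmax(1 - (r / pmax(Rz, 1e-9))^2, 0) +
    1.8 * rough * fineY
  vx[!mask] <- 0; vy[!mask] <- 0

  # RST: eigenframe along jet axis with slight radial tilt in the shear layer
  cAx <- 3 * anisotropy / (anisotropy + 2)
  cT <- 3 / (anisotropy + 2)
  tilt <- 0.35 * exp(-((r - rj)^2) / (2 * wShear^2))
  rSafe <- pmax(r, 1e-9)
  ux <- tilt * X / rSafe
  uy <- tilt * Y / rSafe
  uz <- array(1, dims)
  un <- sqrt(ux^2 + uy^2 + uz^2)
  ux <- ux / un; uy <- uy / un; uz <- uz / un
  s2 <- fluidDensity * sigma^2
  dl <- (cAx - cT)
  R6 <- array(0, c(dims, 6L))
  R6[, , , 1] <- s2 * (cT + dl * ux^2)
  R6[, , , 2] <- s2 * (cT + dl * uy^2)
  R6[, , , 3] <- s2 * (cT + dl * uz^2)
  R6[, , , 4] <- s2 * dl * ux * uy
  R6[, , , 5] <- s2 * dl * ux * uz
  R6[, , , 6] <- s2 * dl * uy * uz

  vel <- array(0, c(dims, 3L))
  vel[, , , 1] <- vx; vel[, , , 2] <- vy; vel[, , , 3] <- vz

  new("PhantomField", velocity = vel, rst = R6, mask = mask,
      spacing = spacing, fluidDensity = fluidDensity,
      seed = as.integer(seed),
      params = list(dims = dims, spacing = spacing, stenosis = stenosis,
                    peakVelocity = peakVelocity, peakIvsd = peakIvsd,
                    vesselRadius = R0, fluidDensity = fluidDensity,
                    anisotropy = anisotropy, perturbation = perturbation,
                    seed = as.integer(seed)))
}

#' Scalar IVSD volume of a phantom or tensor field
#'
#' Direction-averaged intra-voxel standard deviation
#' \eqn{\sqrt{\mathrm{tr}(R)/(3\rho)}} per voxel.
#'
#' @param field a [PhantomField-class], or a tensor volume [nx,ny,nz,6] (Pa)
#'   if `rho` is given.
#' @param rho density, kg/m^3 (taken from the phantom when omitted).
#' @return IVSD volume, m/s.
#' @export
ivsdVolume <- function(field, rho = NULL) {
  if (is(field, "PhantomField")) {
    rho <- field@fluidDensity
    R6 <- field@rst
  } else R6 <- field
  if (is.null(rho)) stop("rho required for a bare tensor volume")
  sqrt(pmax(R6[, , , 1] + R6[, , , 2] + R6[, , , 3], 0) / (3 * rho))
}

#' Relative IVSD histogram over the lumen
#'
#' Relative probability p(sigma) of IVSD values over the masked voxels,
#' normalized to sum to 1.
#'
#' @param field a [PhantomField-class].
#' @param breaks histogram bin edges, m/s (default 40 bins from 0 to a bit
#'   above the field maximum).
#' @return data.frame with columns `mid` (bin center, m/s) and `p`.
#' @export
ivsdHistogram <- function(field, breaks = NULL) {
  stopifnot(is(field, "PhantomField"))
  iv <- ivsdVolume(field)[field@mask]
  if (!length(iv)) stop("empty lumen mask")
  if (is.null(breaks))
    breaks <- seq(0, max(iv) * 1.001 + 1e-9, length.out = 41L)
  h <- hist(iv, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, p = h$counts / sum(h$counts))
}
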