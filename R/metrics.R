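# Derived turbulence quantities: turbulent kinetic energy, maximum principal
# turbulent shear stress, component-wise median filtering of tensor volumes
# and kernel-density distribution summaries.

#' Turbulent kinetic energy
#'
#' TKE per unit volume from the tensor diagonal. With the tensor in stress
#' units (Pa, density folded in) this is half the trace; with the tensor in
#' velocity-variance units ((m/s)^2) it is rho/2 times the trace. The
#' `units` tag makes the convention explicit so the density is never applied
#' twice.
#'
#' @param rst tensor volume [nx,ny,nz,6] (components xx,yy,zz,xy,xz,yz), a
#'   single 3x3 matrix, or an nVoxel x 6 matrix.
#' @param units `"Pa"` (default) or `"m2s2"`.
#' @param rho fluid density, kg/m^3; required for `units = "m2s2"`.
#' @return TKE in J/m^3: a volume, scalar or vector matching the input shape.
#' @examples
#' tke(diag(c(200, 200, 200)))                       # 300 J/m^3
#' tke(diag(rep(0.01, 3)), units = "m2s2", rho = 1060)  # 15.9 J/m^3
#' @export
tke <- function(rst, units = c("Pa", "m2s2"), rho = 1060) {
  units <- match.arg(units)
  scale <- if (units == "Pa") 0.5 else {
    assertScalar(rho, "rho", positive = TRUE); rho / 2
  }
  if (is.array(rst) && length(dim(rst)) == 4L) {
    scale * (rst[, , , 1] + rst[, , , 2] + rst[, , , 3])
  } else if (is.matrix(rst) && all(dim(rst) == c(3L, 3L))) {
    scale * sum(diag(rst))
  } else {
    m <- matrix(rst, ncol = 6L)
    scale * rowSums(m[, 1:3, drop = FALSE])
  }
}

#' Maximum principal turbulent shear stress
#'
#' Half the spread of the tensor eigenvalues,
#' \eqn{\tau_{max} = (\delta_1 - \delta_3)/2} with
#' \eqn{\delta_1 \ge \delta_2 \ge \delta_3}: the largest shear stress over
#' all plane orientations. Zero for isotropic tensors. Voxels with
#' non-finite entries return NA (to be excluded from the analysis mask).
#'
#' @param rst tensor volume [nx,ny,nz,6], a 3x3 matrix, or nVoxel x 6 matrix
#'   in Pa.
#' @return MPTSS in Pa, matching the input shape.
#' @examples
#' mptss(diag(c(300, 200, 100)))  # 100 Pa
#' @export
mptss <- function(rst) {
  if (is.matrix(rst) && all(dim(rst) == c(3L, 3L)))
    rst <- matrix(rstMatToVec(rst), 1L)
  vol <- is.array(rst) && length(dim(rst)) == 4L
  dims <- if (vol) dim(rst)[1:3]
  m <- matrix(rst, ncol = 6L)
  out <- rep(NA_real_, nrow(m))
  fin <- rowSums(!is.finite(m)) == 0L
  if (any(fin)) {
    ev <- symEigenvalues3(m[fin, , drop = FALSE])
    out[fin] <- (ev[, 1] - ev[, 3]) / 2
  }
  if (vol) array(out, dims) else if (length(out) == 1L) out[[1L]] else out
}

#' Component-wise median filter of a tensor volume
#'
#' Applies a cubic spatial median filter of odd size to each tensor component
#' independently, restricted to the mask: only in-mask voxels contribute to a
#' neighborhood median, out-of-bounds neighbors are nearest-padded, and
#' voxels outside the mask are passed through unchanged.
#'
#' @param rst tensor volume [nx,ny,nz,k] (any number of components).
#' @param mask logical volume; default: everywhere.
#' @param size odd window edge length (default 3).
#' @return filtered tensor volume, same shape.
#' @export
medianFilterRst <- function(rst, mask = NULL, size = 3L) {
  size <- as.integer(size)
  if (size %% 2L != 1L || size < 1L) stop("size must be odd and >= 1")
  dims <- dim(rst)[1:3]
  k <- dim(rst)[4L]
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (size == 1L) return(rst)
  half <- size %/% 2L
  off <- -half:half
  vox <- which(mask, arr.ind = TRUE)
  nb <- expand.grid(dx = off, dy = off, dz = off)
  nN <- nrow(nb)
  nV <- nrow(vox)
  # neighbor linear indices with nearest-edge clamping
  ix <- pmin(pmax(rep(vox[, 1], nN) + rep(nb$dx, each = nV), 1L), dims[1])
  iy <- pmin(pmax(rep(vox[, 2], nN) + rep(nb$dy, each = nV), 1L), dims[2])
  iz <- pmin(pmax(rep(vox[, 3], nN) + rep(nb$dz, each = nV), 1L), dims[3])
  lin <- ix + (iy - 1L) * dims[1] + (iz - 1L) * dims[1] * dims[2]
  inMask <- matrix(as.vector(mask)[lin], nV, nN)
  complete <- rowSums(inMask) == nN
  out <- rst
  nSpatial <- prod(dims)
  for (comp in seq_len(k)) {
    compVec <- as.vector(rst)[(comp - 1L) * nSpatial + seq_len(nSpatial)]
    vals <- matrix(compVec[lin], nV, nN)
    med <- numeric(nV)
    if (any(complete))
      med[complete] <- rowMedianOdd(vals[complete, , drop = FALSE])
    if (any(!complete)) {
      v2 <- vals[!complete, , drop = FALSE]
      v2[!inMask[!complete, , drop = FALSE]] <- NA_real_
      med[!complete] <- apply(v2, 1L, median, na.rm = TRUE)
    }
    tmp <- out[, , , comp]
    tmp[mask] <- med
    out[, , , comp] <- tmp
  }
  out
}

# Row-wise median of a matrix with an odd number of columns, via rank
# counting (no per-row sort). Ties are handled by the rank interval test.
rowMedianOdd <- function(vals) {
  nN <- ncol(vals)
  m <- (nN + 1L) %/% 2L
  med <- rep(NA_real_, nrow(vals))
  todo <- rep(TRUE, nrow(vals))
  for (j in seq_len(nN)) {
    if (!any(todo)) break
    vj <- vals[, j]
    less <- rowSums(vals < vj)
    eq <- rowSums(vals == vj)
    hit <- todo & less < m & m <= less + eq
    med[hit] <- vj[hit]
    todo <- todo & !hit
  }
  med
}

#' Gaussian kernel density summary of a value distribution
#'
#' Gaussian KDE (Scott's rule-of-thumb bandwidth by default) evaluated on a
#' regular grid, together with the sample mean and standard deviation.
#'
#' @param values numeric vector, length >= 2.
#' @param bw bandwidth: `"scott"` (default, [stats::bw.nrd()]) or a numeric
#'   value.
#' @param n number of grid points.
#' @return list with `x` (grid), `density`, `mean`, `sd` and `bw`.
#' @examples
#' distributionSummary(c(1, 2, 3))[c("mean", "sd")]
#' @export
distributionSummary <- function(values, bw = "scott", n = 512L) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values)))
    stop("need at least 2 finite values")
  bwVal <- if (identical(bw, "scott")) bw.nrd(values) else
    assertScalar(bw, "bw", positive = TRUE)
  d <- density(values, bw = bwVal, kernel = "gaussian", n = n,
               from = min(values) - 4 * bwVal, to = max(values) + 4 * bwVal)
  list(x = d$x, density = d$y, mean = mean(values), sd = sd(values),
       bw = bwVal)
}

#' Turbulence maps from an estimated tensor volume
#'
#' Bundles [tke()] and [mptss()] over a mask, removing voxels with
#' non-finite tensors from the mask.
#'
#' @param rst tensor volume [nx,ny,nz,6], Pa.
#' @param mask logical volume.
#' @return list with `tke` (J/m^3), `mptss` (Pa) and the cleaned `mask`.
#' @export
turbulenceMaps <- function(rst, mask) {
  tkeVol <- tke(rst)
  mptssVol <- mptss(rst)
  ok <- mask & is.finite(mptssVol) & is.finite(tkeVol)
  tkeVol[!ok] <- 0; mptssVol[!ok] <- 0
  list(tke = tkeVol, mptss = mptssVol, mask = ok)
}
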