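# S4 classes for flow states, encoding schemes, image stacks, phantoms and
# binned k-space. RST volumes are stored as [nx, ny, nz, 6] arrays with
# component order (xx, yy, zz, xy, xz, yz) throughout the package.

RST_COMPONENTS <- c("xx", "yy", "zz", "xy", "xz", "yz")

#' Per-voxel flow state: mean velocity and Reynolds stress tensor
#'
#' Holds the time-averaged velocity vector (m/s), the symmetric Reynolds
#' stress tensor (Pa, fluid density folded in) and the fluid density (kg/m^3)
#' for a single voxel. Velocity fluctuations v' around the mean have
#' covariance R / rho.
#'
#' @slot meanVelocity numeric(3), m/s.
#' @slot rst 3x3 symmetric matrix, Pa. Diagonal entries are rho * variances
#'   and must be non-negative.
#' @slot fluidDensity positive scalar, kg/m^3.
#' @export
setClass("VoxelFlowState",
  representation(meanVelocity = "numeric", rst = "matrix",
                 fluidDensity = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@meanVelocity) != 3L ||
        !all(is.finite(object@meanVelocity)))
      msg <- c(msg, "meanVelocity must be a finite 3-vector")
    R <- object@rst
    if (!is.numeric(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R))) {
      msg <- c(msg, "rst must be a finite 3x3 matrix")
    } else {
      if (max(abs(R - t(R))) > 1e-8 * max(1, max(abs(R))))
        msg <- c(msg, "rst must be symmetric")
      if (any(diag(R) < -1e-10 * max(1, max(abs(R)))))
        msg <- c(msg, "rst diagonal entries must be non-negative")
    }
    if (length(object@fluidDensity) != 1L || !is.finite(object@fluidDensity) ||
        object@fluidDensity <= 0)
      msg <- c(msg, "fluidDensity must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' @describeIn VoxelFlowState-class Constructor.
#' @param meanVelocity numeric(3) mean velocity, m/s.
#' @param rst symmetric 3x3 Reynolds stress tensor, Pa.
#' @param fluidDensity fluid density, kg/m^3 (default blood, 1060).
#' @return A `VoxelFlowState` object.
#' @examples
#' voxelFlowState(c(1, 0, 0), diag(c(30, 20, 10)))
#' @export
voxelFlowState <- function(meanVelocity, rst, fluidDensity = 1060) {
  new("VoxelFlowState", meanVelocity = as.numeric(meanVelocity),
      rst = rst, fluidDensity = as.numeric(fluidDensity))
}

#' Single velocity-encoding vector
#'
#' A bipolar velocity encoding characterized by a unit direction and a VENC
#' (the velocity producing a phase of pi). The first-moment vector is
#' kv = (pi / VENC) * direction, in rad s/m.
#'
#' @slot direction unit 3-vector.
#' @slot venc positive scalar, m/s.
#' @export
setClass("EncodingVector",
  representation(direction = "numeric", venc = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- object@direction
    if (length(d) != 3L || !all(is.finite(d)) ||
        abs(sqrt(sum(d^2)) - 1) > 1e-8)
      msg <- c(msg, "direction must be a unit 3-vector")
    if (length(object@venc) != 1L || !is.finite(object@venc) ||
        object@venc <= 0)
      msg <- c(msg, "venc must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' @describeIn EncodingVector-class Constructor; the direction is normalized.
#' @param direction 3-vector (normalized internally).
#' @param venc VENC in m/s, > 0.
#' @return An `EncodingVector` object.
#' @export
encodingVector <- function(direction, venc) {
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("direction must be a nonzero 3-vector")
  new("EncodingVector", direction = direction / nrm, venc = as.numeric(venc))
}

#' @describeIn EncodingVector-class First gradient-moment vector
#'   kv = (pi/VENC) * direction, rad s/m.
#' @param enc An `EncodingVector`.
#' @export
kvVector <- function(enc) {
  stopifnot(is(enc, "EncodingVector"))
  computeKv(enc@venc) * enc@direction
}

#' Multi-VENC six-direction encoding scheme
#'
#' A set of encoding directions (rows of a matrix, unit norm) each acquired at
#' several VENCs, plus an optional flux-compensated reference (kv = 0)
#' measurement. The default is the 19-point scheme: the six canonical
#' tensor-encoding directions at VENCs 0.5 / 1.5 / 4.5 m/s plus one reference.
#'
#' @slot directions n x 3 matrix of unit row vectors; the quadratic design
#'   matrix derived from them must have full rank 6 for tensor recovery.
#' @slot vencs numeric vector of VENC values (m/s) applied to every direction.
#' @slot includesReference logical; whether the kv = 0 measurement is part of
#'   the scheme.
#' @export
setClass("EncodingScheme",
  representation(directions = "matrix", vencs = "numeric",
                 includesReference = "logical"),
  validity = function(object) {
    msg <- character()
    D <- object@directions
    if (!is.numeric(D) || ncol(D) != 3L || !all(is.finite(D)))
      msg <- c(msg, "directions must be a numeric n x 3 matrix")
    else {
      if (any(abs(sqrt(rowSums(D^2)) - 1) > 1e-8))
        msg <- c(msg, "every direction must have unit norm")
      if (nrow(D) >= 6L) {
        H <- quadraticDesign(D)
        if (qr(H)$rank < 6L)
          msg <- c(msg, "quadratic design matrix must have rank 6")
      }
    }
    if (!length(object@vencs) || any(!is.finite(object@vencs)) ||
        any(object@vencs <= 0))
      msg <- c(msg, "vencs must be positive and finite")
    if (length(object@includesReference) != 1L)
      msg <- c(msg, "includesReference must be a single logical")
    if (length(msg)) msg else TRUE
  })

#' @describeIn EncodingScheme-class Constructor. Defaults reproduce the
#'   19-point scheme (6 directions x 3 VENCs + reference).
#' @param directions n x 3 matrix of directions (rows normalized).
#' @param vencs VENC values in m/s.
#' @param includesReference include the kv = 0 reference measurement?
#' @return An `EncodingScheme` object.
#' @examples
#' sch <- encodingScheme()
#' nEncodings(sch)  # 19
#' @export
encodingScheme <- function(directions = buildDirections(),
                           vencs = c(0.5, 1.5, 4.5),
                           includesReference = TRUE) {
  directions <- as.matrix(directions)
  directions <- directions / sqrt(rowSums(directions^2))
  new("EncodingScheme", directions = directions,
      vencs = as.numeric(sort(vencs)),
      includesReference = isTRUE(includesReference))
}

#' Synthetic ground-truth flow field on a fine grid
#'
#' Dense voxelized flow field: mean-velocity vector and RST per voxel inside a
#' lumen mask, zero outside. Generated by [generateJetPhantom()].
#'
#' @slot velocity numeric array [nx, ny, nz, 3], m/s.
#' @slot rst numeric array [nx, ny, nz, 6], Pa, components (xx,yy,zz,xy,xz,yz);
#'   positive semidefinite inside the mask, zero outside.
#' @slot mask logical array [nx, ny, nz], lumen mask.
#' @slot spacing isotropic grid spacing, mm.
#' @slot fluidDensity kg/m^3.
#' @slot seed integer seed the field was generated with.
#' @slot params list of generator parameters (for provenance / metadata).
#' @export
setClass("PhantomField",
  representation(velocity = "array", rst = "array", mask = "array",
                 spacing = "numeric", fluidDensity = "numeric",
                 seed = "integer", params = "list"),
  validity = function(object) {
    msg <- character()
    dv <- dim(object@velocity); dr <- dim(object@rst); dm <- dim(object@mask)
    if (length(dv) != 4L || dv[4L] != 3L)
      msg <- c(msg, "velocity must be [nx, ny, nz, 3]")
    if (length(dr) != 4L || dr[4L] != 6L)
      msg <- c(msg, "rst must be [nx, ny, nz, 6]")
    if (length(dm) != 3L || !identical(dm, dv[1:3]) || !identical(dm, dr[1:3]))
      msg <- c(msg, "mask dims must match velocity/rst grids")
    if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
    if (object@fluidDensity <= 0) msg <- c(msg, "fluidDensity must be > 0")
    out <- !object@mask
    if (length(msg) == 0L) {
      vOut <- abs(object@velocity) * as.numeric(out)
      rOut <- abs(object@rst) * as.numeric(out)
      if (max(vOut) > 0 || max(rOut) > 0)
        msg <- c(msg, "velocity and rst must vanish outside the mask")
    }
    if (length(msg)) msg else TRUE
  })

#' Stack of complex encoded image volumes
#'
#' One complex image volume per velocity encoding (direction x VENC) plus the
#' reference volume, on a shared grid. The `index` table maps the 4th array
#' dimension to (direction row, VENC); the reference row has `direction = NA`.
#'
#' @slot volumes complex array [nx, ny, nz, nEnc].
#' @slot index data.frame with columns `direction` (integer row index into the
#'   scheme's direction matrix, NA for reference) and `venc` (m/s, NA for
#'   reference).
#' @slot scheme the [EncodingScheme-class] the stack was encoded with.
#' @slot spacing grid spacing, mm.
#' @slot mask logical analysis mask (lumen), same grid.
#' @slot snr target SNR in dB (`Inf` if noiseless).
#' @slot noiseSd realized per-channel noise standard deviation (0 if none).
#' @slot seed integer seed used for the noise draw.
#' @export
setClass("EncodedImageStack",
  representation(volumes = "array", index = "data.frame",
                 scheme = "EncodingScheme", spacing = "numeric",
                 mask = "array", snr = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@volumes)
    if (length(d) != 4L)
      msg <- c(msg, "volumes must be a 4-d array [nx, ny, nz, nEnc]")
    else {
      if (nrow(object@index) != d[4L])
        msg <- c(msg, "index must have one row per encoded volume")
      if (!identical(dim(object@mask), d[1:3]))
        msg <- c(msg, "mask dims must match the image grid")
    }
    if (!all(c("direction", "venc") %in% names(object@index)))
      msg <- c(msg, "index needs columns 'direction' and 'venc'")
    else if (!any(is.na(object@index$direction)))
      msg <- c(msg, "reference volume (direction = NA) missing")
    if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Undersampled k-space sorted into cardiac phases and respiratory states
#'
#' Complex Cartesian k-space for one velocity encoding, binned along cardiac
#' phase and respiratory state. The readout direction (first array dimension)
#' is fully sampled; undersampling lives in the phase-encode (ky, kz) plane.
#'
#' @slot data complex array [nkx, nky, nkz, nPhases, nStates]; zero where the
#'   mask is FALSE.
#' @slot mask logical array [nky, nkz, nPhases, nStates], sampled phase-encode
#'   points per frame.
#' @slot shared logical array like `mask`, TRUE where a point was borrowed by
#'   view sharing rather than acquired.
#' @export
setClass("BinnedKSpace",
  representation(data = "array", mask = "array", shared = "array"),
  validity = function(object) {
    msg <- character()
    dd <- dim(object@data); dm <- dim(object@mask)
    if (length(dd) != 5L) msg <- c(msg, "data must be 5-d [kx,ky,kz,phase,state]")
    if (length(dm) != 4L) msg <- c(msg, "mask must be 4-d [ky,kz,phase,state]")
    if (length(dd) == 5L && length(dm) == 4L && !identical(dd[2:5], dm))
      msg <- c(msg, "mask dims must match data dims 2:5")
    if (!identical(dim(object@shared), dm))
      msg <- c(msg, "shared flags must match mask dims")
    if (length(msg) == 0L) {
      off <- sweep(abs(object@data), 2:5, as.numeric(object@mask), "*")
      if (max(abs(object@data)) > 0 &&
          max(abs(abs(object@data) - off)) > 0)
        msg <- c(msg, "data must be zero where the mask is FALSE")
    }
    if (length(msg)) msg else TRUE
  })

#' @describeIn BinnedKSpace-class Constructor; zeroes data outside the mask.
#' @param data complex array [nkx, nky, nkz, nPhases, nStates].
#' @param mask logical array [nky, nkz, nPhases, nStates].
#' @param shared optional logical array like `mask` (default all FALSE).
#' @return A `BinnedKSpace` object.
#' @export
binnedKSpace <- function(data, mask, shared = NULL) {
  if (is.null(shared)) shared <- array(FALSE, dim(mask))
  data <- sweep(data, 2:5, as.numeric(mask), "*")
  new("BinnedKSpace", data = data, mask = mask, shared = shared)
}

#' Locally low-rank reconstruction settings
#'
#' @slot blockSize edge length of the cubic image blocks whose Casorati
#'   matrices are rank-penalized (voxels; in-vivo scale default 22, scale
#'   down proportionally for small test volumes).
#' @slot lambda nuclear-norm regularization weight, relative to data
#'   normalized so the zero-filled reconstruction has unit maximum magnitude.
#' @slot lambdaStart starting weight for continuation (annealed geometrically
#'   down to `lambda`); equal to `lambda` disables continuation.
#' @slot maxIter maximum number of proximal-gradient iterations.
#' @slot tol relative objective-change stopping tolerance.
#' @slot accelerate logical, use FISTA-style acceleration.
#' @slot cycleSpin logical, random (seeded) block-grid shift per iteration.
#' @slot seed integer seed for cycle spinning.
#' @export
setClass("LlrConfig",
  representation(blockSize = "integer", lambda = "numeric",
                 lambdaStart = "numeric", maxIter = "integer",
                 tol = "numeric", accelerate = "logical",
                 cycleSpin = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@blockSize < 1L) msg <- c(msg, "blockSize must be >= 1")
    if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
    if (object@lambdaStart < object@lambda)
      msg <- c(msg, "lambdaStart must be >= lambda")
    if (object@maxIter < 1L) msg <- c(msg, "maxIter must be >= 1")
    if (object@tol < 0) msg <- c(msg, "tol must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' @describeIn LlrConfig-class Constructor with in-vivo-scale defaults.
#' @param blockSize block edge length in voxels.
#' @param lambda regularization weight.
#' @param lambdaStart continuation start weight (default: `lambda`, i.e. no
#'   continuation).
#' @param maxIter iteration cap.
#' @param tol relative objective-change tolerance.
#' @param accelerate use FISTA acceleration (objective then no longer
#'   guaranteed monotone).
#' @param cycleSpin random block-grid shift per iteration (seeded).
#' @param seed integer seed for cycle spinning.
#' @return An `LlrConfig` object.
#' @export
llrConfig <- function(blockSize = 22L, lambda = 0.005,
                      lambdaStart = lambda, maxIter = 50L,
                      tol = 1e-6, accelerate = FALSE, cycleSpin = FALSE,
                      seed = 1L) {
  new("LlrConfig", blockSize = as.integer(blockSize),
      lambda = as.numeric(lambda), lambdaStart = as.numeric(lambdaStart),
      maxIter = as.integer(maxIter), tol = as.numeric(tol),
      accelerate = isTRUE(accelerate), cycleSpin = isTRUE(cycleSpin),
      seed = as.integer(seed))
}
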