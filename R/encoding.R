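# Construction and analysis of the multi-VENC six-direction encoding scheme:
# kv/VENC conversions, the canonical direction set, the quadratic design
# matrix for tensor recovery, the optimal-VENC rule and sensitivity curves.

#' First gradient moment from VENC
#'
#' kv = pi / VENC (rad s/m): the encoding strength at which a velocity equal
#' to VENC accrues a phase of pi.
#'
#' @param venc VENC in m/s, > 0 (vectorized).
#' @return kv in rad s/m.
#' @examples
#' computeKv(c(0.5, 1.5, 4.5))
#' @export
computeKv <- function(venc) {
  if (any(!is.finite(venc)) || any(venc <= 0))
    stop("venc must be finite and > 0")
  pi / venc
}

#' Canonical six-direction tensor-encoding set
#'
#' Three Cartesian axes plus the three face diagonals (entries 1/sqrt(2)).
#' Together with a reference measurement this direction set determines all
#' six unique entries of a symmetric tensor from direction-wise variances.
#'
#' @return 6 x 3 matrix of unit row vectors.
#' @examples
#' buildDirections()
#' @export
buildDirections <- function() {
  s <- 1 / sqrt(2)
  matrix(c(1, 0, 0,
           0, 1, 0,
           0, 0, 1,
           s, s, 0,
           s, 0, s,
           0, s, s), nrow = 6L, byrow = TRUE)
}

#' Quadratic design matrix for tensor recovery
#'
#' Row i maps the packed tensor (xx, yy, zz, xy, xz, yz) to the variance
#' observed along direction d_i:
#' (d_x^2, d_y^2, d_z^2, 2 d_x d_y, 2 d_x d_z, 2 d_y d_z).
#' Because each encoding's first moment is kv = |kv| d with unit d, the
#' normalization by |kv|^2 cancels and the design depends on directions only.
#'
#' @param directions n x 3 matrix of unit row vectors.
#' @return n x 6 design matrix.
#' @export
quadraticDesign <- function(directions) {
  D <- as.matrix(directions)
  cbind(D[, 1]^2, D[, 2]^2, D[, 3]^2,
        2 * D[, 1] * D[, 2], 2 * D[, 1] * D[, 3], 2 * D[, 2] * D[, 3])
}

#' Optimal VENC for a given turbulence intensity
#'
#' Setting the second derivative of the signal with respect to sigma to zero
#' places the encoding at the inflection point of the attenuation curve,
#' giving kv = 1/sigma, i.e. VENC = pi * sigma.
#'
#' @param sigma expected IVSD, m/s, > 0 (vectorized).
#' @return optimal VENC, m/s.
#' @examples
#' optimalVenc(0.2)     # 0.628 m/s
#' optimalVenc(0.4775)  # ~1.5 m/s
#' @export
optimalVenc <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be finite and > 0")
  pi * sigma
}

#' Magnitude sensitivity curve of one VENC
#'
#' Normalized signal magnitude exp(-sigma^2 kv^2 / 2) over a grid of IVSD
#' values, for one VENC. Useful to visualize the limited sigma range over
#' which a single encoding is informative.
#'
#' @param venc VENC, m/s.
#' @param sigmaGrid IVSD values, m/s, >= 0.
#' @return numeric vector of normalized magnitudes, strictly decreasing in
#'   sigma (for sigma > 0).
#' @export
sensitivityCurve <- function(venc, sigmaGrid) {
  assertScalar(venc, "venc", positive = TRUE)
  if (any(!is.finite(sigmaGrid)) || any(sigmaGrid < 0))
    stop("sigmaGrid must be finite and >= 0")
  kv <- computeKv(venc)
  exp(-sigmaGrid^2 * kv^2 / 2)
}

#' Enumerate the encodings of a scheme
#'
#' Expands an [EncodingScheme-class] into one row per acquired volume: the
#' reference first (direction NA), then directions x VENCs in direction-major
#' order.
#'
#' @param scheme an `EncodingScheme`.
#' @return data.frame with columns `direction` (row index, NA for reference)
#'   and `venc` (NA for reference).
#' @export
schemeIndex <- function(scheme) {
  stopifnot(is(scheme, "EncodingScheme"))
  nd <- nrow(scheme@directions)
  idx <- expand.grid(venc = scheme@vencs, direction = seq_len(nd))
  idx <- idx[order(idx$direction, idx$venc), c("direction", "venc")]
  if (scheme@includesReference)
    idx <- rbind(data.frame(direction = NA_integer_, venc = NA_real_), idx)
  rownames(idx) <- NULL
  idx
}

#' Serialize / read an encoding scheme as YAML
#'
#' Plain-text round-trip of the scheme: directions (row-wise), VENC list and
#' reference flag.
#'
#' @param scheme an [EncodingScheme-class].
#' @param path file path.
#' @return `writeEncodingScheme` returns the path invisibly;
#'   `readEncodingScheme` returns the scheme.
#' @export
writeEncodingScheme <- function(scheme, path) {
  stopifnot(is(scheme, "EncodingScheme"))
  yaml::write_yaml(list(
    directions = apply(scheme@directions, 1L, as.numeric, simplify = FALSE),
    vencs = as.numeric(scheme@vencs),
    includes_reference = scheme@includesReference), path)
  invisible(path)
}

#' @rdname writeEncodingScheme
#' @export
readEncodingScheme <- function(path) {
  x <- yaml::read_yaml(path)
  encodingScheme(
    directions = do.call(rbind, lapply(x$directions, as.numeric)),
    vencs = as.numeric(x$vencs),
    includesReference = isTRUE(x$includes_reference))
}
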