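# Accessor generics and show methods. Slot access from user code should go
# through these.

#' @name accessors
#' @title Accessors for turbmri S4 objects
#' @description Small accessor generics: mean velocity, RST, densities, masks,
#'   directions, VENCs and grid spacing.
#' @param object an S4 object from this package.
#' @return The slot value (see the individual class documentation for units).
NULL

#' @rdname accessors
#' @export
setGeneric("meanVelocity", function(object) standardGeneric("meanVelocity"))
#' @rdname accessors
#' @export
setGeneric("rstTensor", function(object) standardGeneric("rstTensor"))
#' @rdname accessors
#' @export
setGeneric("fluidDensity", function(object) standardGeneric("fluidDensity"))
#' @rdname accessors
#' @export
setGeneric("lumenMask", function(object) standardGeneric("lumenMask"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("directions", function(object) standardGeneric("directions"))
#' @rdname accessors
#' @export
setGeneric("vencs", function(object) standardGeneric("vencs"))
#' @rdname accessors
#' @export
setGeneric("nEncodings", function(object) standardGeneric("nEncodings"))
#' @rdname accessors
#' @export
setGeneric("encodingIndex", function(object) standardGeneric("encodingIndex"))
#' @rdname accessors
#' @export
setGeneric("stackVolumes", function(object) standardGeneric("stackVolumes"))
#' @rdname accessors
#' @export
setGeneric("samplingMask", function(object) standardGeneric("samplingMask"))
#' @rdname accessors
#' @export
setGeneric("kspaceData", function(object) standardGeneric("kspaceData"))
#' @rdname accessors
#' @export
setGeneric("sharedMask", function(object) standardGeneric("sharedMask"))

#' @rdname accessors
#' @export
setMethod("meanVelocity", "VoxelFlowState", function(object) object@meanVelocity)
#' @rdname accessors
#' @export
setMethod("rstTensor", "VoxelFlowState", function(object) object@rst)
#' @rdname accessors
#' @export
setMethod("fluidDensity", "VoxelFlowState", function(object) object@fluidDensity)

#' @rdname accessors
#' @export
setMethod("meanVelocity", "PhantomField", function(object) object@velocity)
#' @rdname accessors
#' @export
setMethod("rstTensor", "PhantomField", function(object) object@rst)
#' @rdname accessors
#' @export
setMethod("fluidDensity", "PhantomField", function(object) object@fluidDensity)
#' @rdname accessors
#' @export
setMethod("lumenMask", "PhantomField", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "PhantomField", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("directions", "EncodingScheme", function(object) object@directions)
#' @rdname accessors
#' @export
setMethod("vencs", "EncodingScheme", function(object) object@vencs)
#' @rdname accessors
#' @export
setMethod("nEncodings", "EncodingScheme", function(object)
  nrow(object@directions) * length(object@vencs) +
    as.integer(object@includesReference))

#' @rdname accessors
#' @export
setMethod("stackVolumes", "EncodedImageStack", function(object) object@volumes)
#' @rdname accessors
#' @export
setMethod("encodingIndex", "EncodedImageStack", function(object) object@index)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "EncodedImageStack", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("lumenMask", "EncodedImageStack", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("nEncodings", "EncodedImageStack", function(object)
  dim(object@volumes)[4L])

#' @rdname accessors
#' @export
setMethod("samplingMask", "BinnedKSpace", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("kspaceData", "BinnedKSpace", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("sharedMask", "BinnedKSpace", function(object) object@shared)

setMethod("show", "VoxelFlowState", function(object) {
  cat("VoxelFlowState\n")
  cat("  mean velocity [m/s]:", sprintf("%.4g", object@meanVelocity), "\n")
  cat("  TKE [J/m^3]:", sprintf("%.4g", sum(diag(object@rst)) / 2),
      " density [kg/m^3]:", object@fluidDensity, "\n")
})

setMethod("show", "EncodingScheme", function(object) {
  cat(sprintf("EncodingScheme: %d directions x %d VENCs%s = %d encodings\n",
              nrow(object@directions), length(object@vencs),
              if (object@includesReference) " + reference" else "",
              nEncodings(object)))
  cat("  VENCs [m/s]:", paste(object@vencs, collapse = ", "), "\n")
})

setMethod("show", "PhantomField", function(object) {
  d <- dim(object@mask)
  cat(sprintf("PhantomField %dx%dx%d @ %.3g mm, %d lumen voxels\n",
              d[1], d[2], d[3], object@spacing, sum(object@mask)))
  iv <- ivsdVolume(object)
  cat(sprintf("  peak IVSD %.3f m/s, peak |v| %.3f m/s, density %g kg/m^3\n",
              max(iv), sqrt(max(rowSums(matrix(object@velocity, ncol = 3)^2))),
              object@fluidDensity))
})

setMethod("show", "EncodedImageStack", function(object) {
  d <- dim(object@volumes)
  cat(sprintf("EncodedImageStack %dx%dx%d, %d encodings @ %.3g mm\n",
              d[1], d[2], d[3], d[4], object@spacing))
  cat(sprintf("  SNR: %s dB (noise sd %.4g)\n",
              format(object@snr), object@noiseSd))
})

setMethod("show", "BinnedKSpace", function(object) {
  dm <- dim(object@mask)
  acc <- frameAcceleration(object)
  cat(sprintf("BinnedKSpace %s, %d phases x %d states\n",
              paste(dim(object@data)[1:3], collapse = "x"), dm[3], dm[4]))
  cat(sprintf("  acceleration: min %.1f / median %.1f / max %.1f\n",
              min(acc), median(acc), max(acc)))
})

setMethod("show", "LlrConfig", function(object) {
  cat(sprintf(
    "LlrConfig: block %d^3, lambda %g, maxIter %d, tol %g%s%s\n",
    object@blockSize, object@lambda, object@maxIter, object@tol,
    if (object@accelerate) ", accelerated" else "",
    if (object@cycleSpin) ", cycle-spinning" else ""))
})
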