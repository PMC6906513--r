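# Volume, k-space and configuration I/O plus run manifests. Image volumes go
# through NIfTI (spacing carried in the header); binned k-space uses base-R
# serialization of a documented list layout (/data, /mask, /dims, /bins,
# /meta); configurations are YAML with strict schema validation.

configError <- function(msg)
  stop(structure(class = c("turbmri_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))

inputError <- function(msg)
  stop(structure(class = c("turbmri_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))

#' Write / read a volume as NIfTI with spacing and JSON metadata
#'
#' Scalar ([nx,ny,nz]) or multi-component ([nx,ny,nz,k]) volumes are stored
#' as 3-d/4-d NIfTI with the isotropic spacing in the header (mm). Tensor
#' volumes use k = 6 with the fixed component order (xx, yy, zz, xy, xz,
#' yz); vector volumes k = 3 (x, y, z). Optional metadata is written to a
#' `.json` sidecar and restored on read.
#'
#' @param vol numeric array, 3-d or 4-d.
#' @param path output path (`.nii` / `.nii.gz`).
#' @param spacing isotropic voxel size, mm.
#' @param metadata optional list, serialized to a JSON sidecar.
#' @return `writeVolume` the path, invisibly; `readVolume` a list with
#'   `data`, `spacing` and `metadata` (NULL if no sidecar).
#' @export
writeVolume <- function(vol, path, spacing, metadata = NULL) {
  assertScalar(spacing, "spacing", positive = TRUE)
  nd <- length(dim(vol))
  if (!(nd %in% c(3L, 4L))) inputError("volume must be 3-d or 4-d")
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(rep(spacing, 3L), if (nd == 4L) 1)
  RNifti::writeNifti(img, path)
  if (!is.null(metadata))
    jsonlite::write_json(metadata, sidecarPath(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(path)
}

sidecarPath <- function(path)
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) inputError(paste("no such volume:", path))
  img <- RNifti::readNifti(path)
  meta <- NULL
  sp <- sidecarPath(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  list(data = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[1], metadata = meta)
}

#' Write / read a phantom as NIfTI volumes plus a JSON sidecar
#'
#' The phantom is stored as three NIfTI files (`velocity` with 3 components,
#' `rst` with 6 components in (xx,yy,zz,xy,xz,yz) order, and `mask`) plus
#' `phantom.json` holding every generator parameter and the seed.
#'
#' @param field a [PhantomField-class].
#' @param dir output directory (created if needed).
#' @return `writePhantom` the directory, invisibly; `readPhantom` the
#'   [PhantomField-class].
#' @export
writePhantom <- function(field, dir) {
  stopifnot(is(field, "PhantomField"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(field@velocity, file.path(dir, "velocity.nii.gz"),
              field@spacing)
  writeVolume(field@rst, file.path(dir, "rst.nii.gz"), field@spacing)
  writeVolume(array(as.numeric(field@mask), dim(field@mask)),
              file.path(dir, "mask.nii.gz"), field@spacing)
  jsonlite::write_json(
    c(field@params, list(fluidDensity = field@fluidDensity,
                         componentOrder = RST_COMPONENTS)),
    file.path(dir, "phantom.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(dir) {
  pj <- file.path(dir, "phantom.json")
  if (!file.exists(pj)) inputError(paste("no phantom at", dir))
  params <- jsonlite::read_json(pj, simplifyVector = TRUE)
  vel <- readVolume(file.path(dir, "velocity.nii.gz"))
  rst <- readVolume(file.path(dir, "rst.nii.gz"))
  msk <- readVolume(file.path(dir, "mask.nii.gz"))
  new("PhantomField", velocity = vel$data, rst = rst$data,
      mask = array(msk$data > 0.5, dim(msk$data)[1:3]),
      spacing = vel$spacing, fluidDensity = params$fluidDensity,
      seed = as.integer(params$seed),
      params = params[setdiff(names(params),
                              c("fluidDensity", "componentOrder"))])
}

#' Write / read an encoded image stack
#'
#' Complex stacks are serialized with their encoding table, scheme, spacing,
#' mask and noise state, as a single-file container.
#'
#' @param stack an [EncodedImageStack-class].
#' @param path file path (`.rds`).
#' @return `writeStack` the path, invisibly; `readStack` the stack.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "EncodedImageStack"))
  saveRDS(list(volumes = stack@volumes, index = stack@index,
               directions = directions(stack@scheme),
               vencs = vencs(stack@scheme),
               includesReference = stack@scheme@includesReference,
               spacing = stack@spacing, mask = stack@mask, snr = stack@snr,
               noiseSd = stack@noiseSd, seed = stack@seed), path)
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  if (!file.exists(path)) inputError(paste("no such stack:", path))
  x <- readRDS(path)
  new("EncodedImageStack", volumes = x$volumes, index = x$index,
      scheme = encodingScheme(x$directions, x$vencs, x$includesReference),
      spacing = x$spacing, mask = x$mask, snr = x$snr, noiseSd = x$noiseSd,
      seed = x$seed)
}

#' Write / read binned k-space
#'
#' Single-file container with the documented layout: `data` (complex array
#' [kx,ky,kz,phase,state]), `mask`, `shared`, `dims`, `bins` (phase/state
#' counts) and `meta`.
#'
#' @param binned a [BinnedKSpace-class].
#' @param path file path (`.rds`).
#' @param meta optional metadata list.
#' @return `writeKSpace` the path, invisibly; `readKSpace` the object (the
#'   metadata is attached as attribute `meta`).
#' @export
writeKSpace <- function(binned, path, meta = list()) {
  stopifnot(is(binned, "BinnedKSpace"))
  dm <- dim(binned@mask)
  saveRDS(list(data = binned@data, mask = binned@mask,
               shared = binned@shared, dims = dim(binned@data),
               bins = list(phases = dm[3], states = dm[4]), meta = meta),
          path)
  invisible(path)
}

#' @rdname writeKSpace
#' @export
readKSpace <- function(path) {
  if (!file.exists(path)) inputError(paste("no such k-space file:", path))
  x <- readRDS(path)
  obj <- new("BinnedKSpace", data = x$data, mask = x$mask,
             shared = x$shared)
  attr(obj, "meta") <- x$meta
  obj
}

# --- run configuration ------------------------------------------------------

configSchema <- list(
  output = NULL, seed = NULL, density = NULL,
  phantom = c("dims", "spacing", "stenosis", "peak_velocity", "peak_ivsd",
              "vessel_radius", "density", "anisotropy", "perturbation"),
  scheme = c("vencs", "include_reference", "directions"),
  experiment = c("snr_list", "factor_list", "n_reps", "median_size",
                 "method"),
  recon = c("block_size", "lambda", "lambda_start", "max_iter", "tol",
            "accelerate", "cycle_spin"))

#' Read and validate a run configuration
#'
#' YAML configuration with sections `phantom`, `scheme`, `experiment` and
#' `recon` plus top-level `output`, `seed` and `density`. Unknown sections or
#' keys are rejected, and defaults are filled in for everything optional.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) inputError(paste("no such config:", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) configError(conditionMessage(e)))
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg configuration list (as parsed from YAML).
#' @export
validateRunConfig <- function(cfg) {
  if (!is.list(cfg)) configError("config must be a mapping")
  unknown <- setdiff(names(cfg), names(configSchema))
  if (length(unknown))
    configError(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  for (sec in intersect(names(cfg), c("phantom", "scheme", "experiment",
                                      "recon"))) {
    bad <- setdiff(names(cfg[[sec]]), configSchema[[sec]])
    if (length(bad))
      configError(paste0("unknown keys in '", sec, "': ",
                         paste(bad, collapse = ", ")))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output <- cfg$output %||% "turbmri-out"
  cfg$density <- as.numeric(cfg$density %||% 1060)
  if (!is.finite(cfg$seed)) configError("seed must be an integer")
  if (cfg$density <= 0) configError("density must be > 0")
  ph <- cfg$phantom %||% list()
  cfg$phantom <- list(
    dims = as.integer(ph$dims %||% c(32L, 32L, 64L)),
    spacing = as.numeric(ph$spacing %||% 0.625),
    stenosis = as.numeric(ph$stenosis %||% 0.64),
    peak_velocity = as.numeric(ph$peak_velocity %||% 2.0),
    peak_ivsd = as.numeric(ph$peak_ivsd %||% 0.8),
    vessel_radius = if (!is.null(ph$vessel_radius))
      as.numeric(ph$vessel_radius),
    density = as.numeric(ph$density %||% 1200),
    anisotropy = as.numeric(ph$anisotropy %||% 2),
    perturbation = as.numeric(ph$perturbation %||% 0.05))
  if (length(cfg$phantom$dims) != 3L || any(cfg$phantom$dims < 4L))
    configError("phantom dims must be 3 integers >= 4")
  if (cfg$phantom$stenosis < 0 || cfg$phantom$stenosis >= 1)
    configError("phantom stenosis must be in [0, 1)")
  sc <- cfg$scheme %||% list()
  cfg$scheme <- list(
    vencs = as.numeric(sc$vencs %||% c(0.5, 1.5, 4.5)),
    include_reference = isTRUE(sc$include_reference %||% TRUE),
    directions = if (!is.null(sc$directions))
      do.call(rbind, lapply(sc$directions, as.numeric)))
  if (any(cfg$scheme$vencs <= 0)) configError("vencs must be > 0")
  ex <- cfg$experiment %||% list()
  cfg$experiment <- list(
    snr_list = as.numeric(ex$snr_list %||% c(40, 30, 20)),
    factor_list = as.integer(ex$factor_list %||% 1L),
    n_reps = as.integer(ex$n_reps %||% 5L),
    median_size = as.integer(ex$median_size %||% 3L),
    method = as.character(ex$method %||% "bayes"))
  if (cfg$experiment$n_reps < 1L) configError("n_reps must be >= 1")
  rc <- cfg$recon %||% list()
  cfg$recon <- list(
    block_size = as.integer(rc$block_size %||% 22L),
    lambda = as.numeric(rc$lambda %||% 0.005),
    lambda_start = as.numeric(rc$lambda_start %||% rc$lambda %||% 0.005),
    max_iter = as.integer(rc$max_iter %||% 50L),
    tol = as.numeric(rc$tol %||% 1e-6),
    accelerate = isTRUE(rc$accelerate %||% FALSE),
    cycle_spin = isTRUE(rc$cycle_spin %||% FALSE))
  if (cfg$recon$lambda < 0) configError("recon lambda must be >= 0")
  cfg
}

#' Write a run manifest
#'
#' JSON record of the configuration hash, base seed and software versions
#' from which a run can be reproduced exactly. Deliberately contains no
#' timestamps so that repeated runs produce bit-identical output trees.
#'
#' @param dir output directory.
#' @param configPath path of the configuration the run used.
#' @param seed base seed of the run.
#' @param inputs named character vector of input file paths to hash.
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(dir, configPath, seed, inputs = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hashes <- if (length(inputs))
    as.list(tools::md5sum(inputs[file.exists(inputs)])) else NULL
  jsonlite::write_json(list(
    config = basename(configPath),
    configHash = unname(tools::md5sum(configPath)),
    seed = as.integer(seed),
    package = as.character(utils::packageVersion("turbmri")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    inputHashes = hashes),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}
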