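## Raster I/O (TIFF) and structured experiment configuration (YAML).

#' Read a raster or stack from a TIFF file
#'
#' Single-page files return a numeric matrix; multi-page files return a
#' 3D array in page-major order \code{(pages, rows, columns)}.  Integer
#' TIFFs are read as stored counts (no 0-1 rescaling).
#'
#' @param path file path.
#' @return numeric matrix or 3D array.
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("cannot read TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  pages <- lapply(pages, function(p) {
    bits <- attr(p, "bits.per.sample")
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra channels
    ## integer TIFFs arrive scaled to [0,1]; restore stored counts.
    ## 32-bit pages are IEEE floats and already carry their values.
    if (!is.null(bits) && bits %in% c(8L, 16L)) p <- p * (2^bits - 1)
    matrix(as.numeric(p), nrow(p), ncol(p))
  })
  if (length(pages) == 1L) return(pages[[1]])
  d <- dim(pages[[1]])
  out <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
  out
}

#' Write a raster or stack to a TIFF file
#'
#' \code{dtype = "float32"} writes 32-bit samples.  Storage through the
#' underlying libtiff binding is unit-range, so values are written as
#' \code{x / scale}: with the default \code{scale = "auto"} the divisor is
#' the smallest power of two not below \code{max(x)}, and it is returned
#' invisibly alongside the path.  Pass \code{scale = 1} for data already
#' in \code{[0, 1]}.  The round trip is exact to one part in \code{2^32}
#' of the scale (the binding quantizes 32-bit samples on that grid).
#' Negative values cannot be represented and are rejected.
#'
#' \code{dtype = "uint16"} writes 16-bit unsigned integer counts: negative
#' values are clipped to 0 with a warning, and with \code{rescale = TRUE}
#' the maximum is mapped to 65535 first.
#'
#' @param x numeric matrix or 3D array \code{(pages, rows, columns)}.
#' @param path output file path.
#' @param dtype \code{"float32"} or \code{"uint16"}.
#' @param rescale for \code{"uint16"}: rescale the maximum to 65535.
#' @param scale for \code{"float32"}: unit-range divisor, or \code{"auto"}.
#' @return list with \code{path} and the \code{scale} used, invisibly.
#' @export
writeRaster <- function(x, path, dtype = c("float32", "uint16"),
                        rescale = FALSE, scale = "auto") {
  dtype <- match.arg(dtype)
  pages <- if (is.matrix(x)) list(x) else {
    stopifnot(length(dim(x)) == 3L)
    lapply(seq_len(dim(x)[1]), function(i) x[i, , ])
  }
  mn <- min(vapply(pages, min, numeric(1)))
  mx <- max(vapply(pages, max, numeric(1)))
  used <- 1
  if (dtype == "uint16") {
    if (mn < 0) {
      warning("negative values clipped to 0 for uint16 output")
      pages <- lapply(pages, function(p) pmax(p, 0))
    }
    if (rescale && mx > 0) pages <- lapply(pages, function(p) p / mx * 65535)
    pages <- lapply(pages, function(p) pmin(round(p), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else {
    if (mn < 0)
      stop("float32 TIFF storage is unit-range; negative values unsupported")
    used <- if (identical(scale, "auto")) {
      if (mx > 1) 2^ceiling(log2(mx)) else 1
    } else as.numeric(scale)
    if (mx / used > 1)
      stop("values exceed the unit range after division by 'scale'")
    pages <- lapply(pages, function(p) p / used)
    tiff::writeTIFF(pages, path, bits.per.sample = 32)
  }
  invisible(list(path = path, scale = used))
}

#' Experiment configuration for the synthetic multiview study
#'
#' @slot phantom a [PhantomSpec-class].
#' @slot psfSigma true blurring PSF standard deviations (axial, lateral)
#'   in pixels; one rotated copy per phantom view angle.
#' @slot schedule a [BlindSchedule-class].
#' @slot initialPsf list describing the Blind-AU PSF initialization:
#'   \code{type} one of \code{"gaussian"} (with \code{sigma}),
#'   \code{"random"} (with \code{seed}) or \code{"file"} (with
#'   \code{path}).
#' @slot rlIterations iterations for the known-PSF Richardson-Lucy
#'   comparison arm.
#' @slot backgroundSize corner-patch side for SNR background regions.
#' @slot outputDir directory for written rasters/traces; \code{""}
#'   disables writing.
#' @export
setClass("ExperimentConfig",
  representation(phantom = "PhantomSpec", psfSigma = "numeric",
                 schedule = "BlindSchedule", initialPsf = "list",
                 rlIterations = "integer", backgroundSize = "integer",
                 outputDir = "character"),
  prototype(psfSigma = c(2.7, 1), initialPsf = list(type = "gaussian",
                                                    sigma = 4),
            rlIterations = 4000L, backgroundSize = 15L, outputDir = ""))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (length(object@psfSigma) != 2 || any(object@psfSigma <= 0))
    msg <- c(msg, "psfSigma must be two positive values")
  if (!identical(object@initialPsf$type %in%
                 c("gaussian", "random", "file"), TRUE))
    msg <- c(msg, "initialPsf$type must be gaussian, random or file")
  if (object@rlIterations < 1) msg <- c(msg, "rlIterations must be >= 1")
  if (object@backgroundSize < 1) msg <- c(msg, "backgroundSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct an experiment configuration
#'
#' Defaults mirror the synthetic study: a two-view 191 x 191 phantom,
#' true PSFs with \eqn{\sigma = (2.7, 1)} px at 0/90 degrees, Blind-AU
#' initialized from an isotropic \eqn{\sigma = 4} px Gaussian, and a
#' 50/50 x 2000 schedule.
#'
#' @param phantom,psfSigma,schedule,initialPsf,rlIterations,backgroundSize,outputDir
#'   see [ExperimentConfig-class].
#' @return an [ExperimentConfig-class].
#' @export
experimentConfig <- function(phantom = PhantomSpec(),
                             psfSigma = c(2.7, 1),
                             schedule = BlindSchedule(),
                             initialPsf = list(type = "gaussian", sigma = 4),
                             rlIterations = 4000L,
                             backgroundSize = 15L,
                             outputDir = "") {
  new("ExperimentConfig", phantom = phantom,
      psfSigma = as.numeric(psfSigma), schedule = schedule,
      initialPsf = initialPsf, rlIterations = as.integer(rlIterations),
      backgroundSize = as.integer(backgroundSize), outputDir = outputDir)
}

#' Read / write an experiment configuration (YAML)
#'
#' The on-disk form is a structured YAML file mirroring the
#' [ExperimentConfig-class] fields; read and write round-trip exactly.
#'
#' @param path YAML file path.
#' @return \code{readExperimentConfig}: an [ExperimentConfig-class];
#'   \code{writeExperimentConfig}: \code{path}, invisibly.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- y$phantom
  sc <- y$schedule
  experimentConfig(
    phantom = PhantomSpec(shape = ph$shape,
                          structureCount = ph$structure_count,
                          vesselWidthRange = ph$vessel_width_range,
                          intensityMax = ph$intensity_max,
                          noiseMean = ph$noise_mean,
                          noiseModel = ph$noise_model,
                          angles = ph$angles,
                          maxViewShift = ph$max_view_shift,
                          seed = ph$seed),
    psfSigma = y$psf_sigma,
    schedule = BlindSchedule(sc$object_iters, sc$psf_iters, sc$cycles,
                             sc$checkpoint_every),
    initialPsf = y$initial_psf,
    rlIterations = y$rl_iterations,
    backgroundSize = y$background_size,
    outputDir = if (is.null(y$output_dir)) "" else y$output_dir)
}

#' @rdname readExperimentConfig
#' @param config an [ExperimentConfig-class].
#' @export
writeExperimentConfig <- function(config, path) {
  stopifnot(is(config, "ExperimentConfig"))
  validObject(config)
  ph <- config@phantom
  sc <- config@schedule
  y <- list(
    phantom = list(shape = as.integer(ph@shape),
                   structure_count = ph@structureCount,
                   vessel_width_range = ph@vesselWidthRange,
                   intensity_max = ph@intensityMax,
                   noise_mean = ph@noiseMean,
                   noise_model = ph@noiseModel,
                   angles = ph@angles,
                   max_view_shift = ph@maxViewShift,
                   seed = ph@seed),
    psf_sigma = config@psfSigma,
    schedule = list(object_iters = sc@objectIters, psf_iters = sc@psfIters,
                    cycles = sc@cycles,
                    checkpoint_every = sc@checkpointEvery),
    initial_psf = config@initialPsf,
    rl_iterations = config@rlIterations,
    background_size = config@backgroundSize,
    output_dir = config@outputDir)
  yaml::write_yaml(y, path)
  invisible(path)
}
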