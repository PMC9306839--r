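#' Parametric anisotropic Gaussian PSF model
#'
#' Describes a light-sheet point spread function as an anisotropic Gaussian,
#' elongated along the detection/scan axis (matrix rows), rotated about the
#' central pixel of an odd-extent raster.
#'
#' @slot sigmaAxial standard deviation along the detection/scan axis
#'   (pixels), the long axis at \code{theta = 0}.
#' @slot sigmaLateral standard deviation along the orthogonal axis (pixels).
#' @slot theta rotation angle about the central pixel, degrees,
#'   counter-clockwise from the row axis.
#' @slot shape raster extents (rows, columns); both must be odd so the
#'   rotation axis is a pixel center.
#'
#' @seealso [rasterizePsf()]
#' @export
setClass("PsfModel",
  representation(sigmaAxial = "numeric", sigmaLateral = "numeric",
                 theta = "numeric", shape = "integer"),
  prototype(sigmaAxial = 2.7, sigmaLateral = 1.0, theta = 0,
            shape = c(191L, 191L)))

setValidity("PsfModel", function(object) {
  msg <- character()
  if (length(object@sigmaAxial) != 1 || !is.finite(object@sigmaAxial) ||
      object@sigmaAxial <= 0)
    msg <- c(msg, "sigmaAxial must be a single positive number")
  if (length(object@sigmaLateral) != 1 || !is.finite(object@sigmaLateral) ||
      object@sigmaLateral <= 0)
    msg <- c(msg, "sigmaLateral must be a single positive number")
  if (length(object@theta) != 1 || !is.finite(object@theta))
    msg <- c(msg, "theta must be a single finite angle in degrees")
  if (length(object@shape) != 2 || any(object@shape < 1))
    msg <- c(msg, "shape must be two positive extents")
  else if (any(object@shape %% 2L == 0L))
    msg <- c(msg, "shape extents must be odd (central-pixel symmetry)")
  if (length(msg)) msg else TRUE
})

#' Construct a PSF model
#'
#' @param sigmaAxial,sigmaLateral Gaussian standard deviations in pixels
#'   along the axial (row) and lateral (column) directions at zero rotation.
#' @param theta rotation angle in degrees about the central pixel.
#' @param shape odd raster extents (rows, columns).
#' @return A [PsfModel-class] object.
#' @examples
#' PsfModel(2.7, 1, theta = 90, shape = c(31, 31))
#' @export
PsfModel <- function(sigmaAxial = 2.7, sigmaLateral = 1.0, theta = 0,
                     shape = c(191L, 191L)) {
  new("PsfModel", sigmaAxial = as.numeric(sigmaAxial),
      sigmaLateral = as.numeric(sigmaLateral), theta = as.numeric(theta),
      shape = as.integer(shape))
}

#' Specification of the synthetic vessel phantom and its measurement
#'
#' Bundles every parameter of the synthetic study: the phantom geometry,
#' the intensity normalization ceiling, the Poisson noise level, the view
#' angles, and the random seed that makes the instance reproducible.
#'
#' @slot shape raster extents (rows, columns); odd by convention so that
#'   PSF rotations act about a pixel center.
#' @slot structureCount number of vessel-like curvilinear structures.
#' @slot vesselWidthRange tubular cross-section width range in pixels.
#' @slot intensityMax normalization ceiling in counts (default \code{2^16}).
#' @slot noiseMean Poisson parameter \eqn{\lambda} in counts
#'   (default \code{2^8}).
#' @slot noiseModel either \code{"scaled-poisson"} (photon-budget shot
#'   noise: the image is measured in photon units with peak mean/variance
#'   \eqn{\lambda}, then rescaled to the ceiling, so zero-signal pixels
#'   stay zero) or \code{"additive"} (a Poisson(\eqn{\lambda}) offset added
#'   to every pixel).  See the methods vignette for why both exist.
#' @slot angles view angles in degrees.
#' @slot maxViewShift largest rigid per-view misalignment (pixels) applied
#'   to non-reference views; drawn uniformly from
#'   \code{-maxViewShift:maxViewShift} per axis.
#' @slot seed integer seed controlling phantom geometry, misalignment and
#'   noise realizations.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", structureCount = "integer",
                 vesselWidthRange = "numeric", intensityMax = "numeric",
                 noiseMean = "numeric", noiseModel = "character",
                 angles = "numeric", maxViewShift = "integer",
                 seed = "integer"),
  prototype(shape = c(191L, 191L), structureCount = 12L,
            vesselWidthRange = c(2, 5), intensityMax = 2^16,
            noiseMean = 2^8, noiseModel = "scaled-poisson",
            angles = c(0, 90), maxViewShift = 8L, seed = 0L))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@shape) != 2 || any(object@shape < 31))
    msg <- c(msg, "shape must be two extents of at least 31 px")
  else if (any(object@shape %% 2L == 0L))
    msg <- c(msg, "shape extents must be odd")
  if (object@structureCount < 0)
    msg <- c(msg, "structureCount must be nonnegative")
  if (length(object@vesselWidthRange) != 2 ||
      any(object@vesselWidthRange <= 0) ||
      diff(object@vesselWidthRange) < 0)
    msg <- c(msg, "vesselWidthRange must be an increasing positive pair")
  if (object@intensityMax <= 0) msg <- c(msg, "intensityMax must be > 0")
  if (object@noiseMean < 0) msg <- c(msg, "noiseMean must be >= 0")
  if (!object@noiseModel %in% c("scaled-poisson", "additive"))
    msg <- c(msg, "noiseModel must be 'scaled-poisson' or 'additive'")
  if (length(object@angles) < 1) msg <- c(msg, "at least one view angle")
  if (object@maxViewShift < 0) msg <- c(msg, "maxViewShift must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a phantom specification
#'
#' Defaults reproduce the synthetic study conditions: a 191 x 191 raster,
#' two orthogonal views (0 and 90 degrees), normalization to \code{2^16}
#' counts and Poisson noise with \eqn{\lambda = 2^8}.
#'
#' @param shape,structureCount,vesselWidthRange,intensityMax,noiseMean,noiseModel,angles,maxViewShift,seed
#'   see the slot documentation in [PhantomSpec-class].
#' @return A [PhantomSpec-class] object.
#' @examples
#' PhantomSpec(seed = 7)
#' @export
PhantomSpec <- function(shape = c(191L, 191L), structureCount = 12L,
                        vesselWidthRange = c(2, 5), intensityMax = 2^16,
                        noiseMean = 2^8, noiseModel = "scaled-poisson",
                        angles = c(0, 90), maxViewShift = 8L, seed = 0L) {
  new("PhantomSpec", shape = as.integer(shape),
      structureCount = as.integer(structureCount),
      vesselWidthRange = as.numeric(vesselWidthRange),
      intensityMax = as.numeric(intensityMax),
      noiseMean = as.numeric(noiseMean), noiseModel = noiseModel,
      angles = as.numeric(angles), maxViewShift = as.integer(maxViewShift),
      seed = as.integer(seed))
}

#' A set of views of one specimen
#'
#' @slot views list of rasters (numeric matrices), one per acquisition
#'   angle, all with identical extents.
#' @slot angles acquisition angle per view, degrees.
#' @slot referenceIndex index of the view used as alignment reference.
#' @export
setClass("ViewSet",
  representation(views = "list", angles = "numeric",
                 referenceIndex = "integer"),
  prototype(views = list(), angles = numeric(), referenceIndex = 1L))

setValidity("ViewSet", function(object) {
  msg <- character()
  m <- length(object@views)
  if (m < 1) msg <- c(msg, "a ViewSet needs at least one view")
  else {
    if (!all(vapply(object@views, is.matrix, logical(1))))
      msg <- c(msg, "all views must be matrices")
    else {
      d <- dim(object@views[[1]])
      same <- vapply(object@views, function(v) identical(dim(v), d),
                     logical(1))
      if (!all(same)) msg <- c(msg, "all views must share one shape")
    }
    if (length(object@angles) != m)
      msg <- c(msg, "one angle per view required")
    if (object@referenceIndex < 1 || object@referenceIndex > m)
      msg <- c(msg, "referenceIndex out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a view set
#'
#' @param views list of rasters with identical extents.
#' @param angles acquisition angles in degrees (default: 90-degree steps).
#' @param referenceIndex which view anchors the alignment (default first).
#' @return A [ViewSet-class] object.
#' @export
ViewSet <- function(views, angles = 90 * (seq_along(views) - 1),
                    referenceIndex = 1L) {
  new("ViewSet", views = views, angles = as.numeric(angles),
      referenceIndex = as.integer(referenceIndex))
}

#' Iteration schedule of the Blind-AU alternation
#'
#' @slot objectIters AU iterations per object block (\eqn{t}).
#' @slot psfIters AU iterations per PSF block (\eqn{t'}).
#' @slot cycles number of outer alternations (\eqn{k}).
#' @slot checkpointEvery cycles between recorded convergence snapshots.
#' @export
setClass("BlindSchedule",
  representation(objectIters = "integer", psfIters = "integer",
                 cycles = "integer", checkpointEvery = "integer"),
  prototype(objectIters = 50L, psfIters = 50L, cycles = 2000L,
            checkpointEvery = 50L))

setValidity("BlindSchedule", function(object) {
  counts <- c(object@objectIters, object@psfIters, object@cycles,
              object@checkpointEvery)
  if (any(counts < 1L)) "all schedule counts must be >= 1" else TRUE
})

#' Construct a Blind-AU iteration schedule
#'
#' The default (50 object iterations, 50 PSF iterations, 2000 cycles) is
#' the full-scale synthetic schedule: \code{2e5} AU iterations in total,
#' \code{1e5} per unknown.
#'
#' @param objectIters,psfIters,cycles,checkpointEvery see
#'   [BlindSchedule-class].
#' @return A [BlindSchedule-class] object.
#' @examples
#' totalIterations(BlindSchedule(50, 50, 2000))
#' @export
BlindSchedule <- function(objectIters = 50L, psfIters = 50L, cycles = 2000L,
                          checkpointEvery = max(1L, as.integer(cycles) %/% 40L)) {
  new("BlindSchedule", objectIters = as.integer(objectIters),
      psfIters = as.integer(psfIters), cycles = as.integer(cycles),
      checkpointEvery = as.integer(checkpointEvery))
}

#' State of a Blind-AU reconstruction
#'
#' @slot objectEstimate current object raster \eqn{o_k}.
#' @slot psfEstimate current unit-sum PSF raster \eqn{h_k}.
#' @slot chi the fixed averaged-autocorrelation input \eqn{\chi_\mu}.
#' @slot cycle number of completed outer cycles.
#' @slot history data.frame of per-checkpoint diagnostics (cycle, object
#'   flux, and - when a measurement was supplied - energy-normalized MSE
#'   and SNR in dB).
#' @export
setClass("ReconstructionState",
  representation(objectEstimate = "matrix", psfEstimate = "matrix",
                 chi = "matrix", cycle = "integer", history = "data.frame"))

setValidity("ReconstructionState", function(object) {
  msg <- character()
  if (min(object@objectEstimate) < 0 || min(object@psfEstimate) < 0)
    msg <- c(msg, "estimates must be nonnegative")
  if (!identical(dim(object@objectEstimate), dim(object@chi)) ||
      !identical(dim(object@psfEstimate), dim(object@chi)))
    msg <- c(msg, "estimates and chi must share one shape")
  if (length(msg)) msg else TRUE
})

#' Axis-wise Gaussian characterization of a PSF-like blob
#'
#' @slot center subpixel blob center per axis (pixels).
#' @slot sigma Gaussian standard deviation per axis (pixels).
#' @slot amplitude fitted peak amplitude above offset, per axis (counts).
#' @slot offset fitted constant background per axis (counts).
#' @slot residual residual standard error per axis.
#' @export
setClass("GaussianFit",
  representation(center = "numeric", sigma = "numeric",
                 amplitude = "numeric", offset = "numeric",
                 residual = "numeric"))

setValidity("GaussianFit", function(object) {
  if (any(object@sigma <= 0)) "sigma must be positive per axis" else TRUE
})
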