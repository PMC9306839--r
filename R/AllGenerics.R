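#' @name accessors
#' @title Accessors for blindAU S4 objects
#' @description Small accessor generics; prefer these over direct slot
#'   access.
#' @param x an object of the documented class.
#' @return The slot value (see each method).
NULL

#' @rdname accessors
#' @export
setGeneric("objectEstimate", function(x) standardGeneric("objectEstimate"))
#' @rdname accessors
#' @export
setGeneric("psfEstimate", function(x) standardGeneric("psfEstimate"))
#' @rdname accessors
#' @export
setGeneric("chiField", function(x) standardGeneric("chiField"))
#' @rdname accessors
#' @export
setGeneric("convergenceHistory",
           function(x) standardGeneric("convergenceHistory"))
#' @rdname accessors
#' @export
setGeneric("totalIterations", function(x) standardGeneric("totalIterations"))
#' @rdname accessors
#' @export
setGeneric("viewRasters", function(x) standardGeneric("viewRasters"))
#' @rdname accessors
#' @export
setGeneric("viewAngles", function(x) standardGeneric("viewAngles"))
#' @rdname accessors
#' @export
setGeneric("psfSigma", function(x) standardGeneric("psfSigma"))

#' @rdname accessors
#' @export
setMethod("objectEstimate", "ReconstructionState",
          function(x) x@objectEstimate)
#' @rdname accessors
#' @export
setMethod("psfEstimate", "ReconstructionState", function(x) x@psfEstimate)
#' @rdname accessors
#' @export
setMethod("chiField", "ReconstructionState", function(x) x@chi)
#' @rdname accessors
#' @export
setMethod("convergenceHistory", "ReconstructionState",
          function(x) x@history)
#' @rdname accessors
#' @export
setMethod("totalIterations", "BlindSchedule",
          function(x) (x@objectIters + x@psfIters) * x@cycles)
#' @rdname accessors
#' @export
setMethod("viewRasters", "ViewSet", function(x) x@views)
#' @rdname accessors
#' @export
setMethod("viewAngles", "ViewSet", function(x) x@angles)
#' @rdname accessors
#' @export
setMethod("psfSigma", "PsfModel",
          function(x) c(axial = x@sigmaAxial, lateral = x@sigmaLateral))
#' @rdname accessors
#' @export
setMethod("psfSigma", "GaussianFit", function(x) x@sigma)

setMethod("show", "PsfModel", function(object) {
  cat(sprintf(
    "PsfModel: anisotropic Gaussian, sigma = (%.3g, %.3g) px, theta = %g deg, %d x %d\n",
    object@sigmaAxial, object@sigmaLateral, object@theta,
    object@shape[1], object@shape[2]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    paste0("PhantomSpec: %d x %d, %d vessels (width %.3g-%.3g px)\n",
           "  ceiling %g counts, Poisson lambda = %g (%s), views at %s deg, seed %d\n"),
    object@shape[1], object@shape[2], object@structureCount,
    object@vesselWidthRange[1], object@vesselWidthRange[2],
    object@intensityMax, object@noiseMean, object@noiseModel,
    paste(object@angles, collapse = "/"), object@seed))
})

setMethod("show", "ViewSet", function(object) {
  d <- dim(object@views[[1]])
  cat(sprintf("ViewSet: %d view(s) of %d x %d at %s deg (reference %d)\n",
              length(object@views), d[1], d[2],
              paste(object@angles, collapse = "/"), object@referenceIndex))
})

setMethod("show", "BlindSchedule", function(object) {
  cat(sprintf(
    "BlindSchedule: %d object + %d PSF iterations per cycle, %d cycles (total %g)\n",
    object@objectIters, object@psfIters, object@cycles,
    totalIterations(object)))
})

setMethod("show", "ReconstructionState", function(object) {
  cat(sprintf(
    "ReconstructionState after %d cycle(s): object %d x %d (flux %.4g), PSF sum %.6f\n",
    object@cycle, nrow(object@objectEstimate), ncol(object@objectEstimate),
    sum(object@objectEstimate), sum(object@psfEstimate)))
  if (nrow(object@history))
    cat(sprintf("  history: %d checkpoint(s), last at cycle %d\n",
                nrow(object@history), max(object@history$cycle)))
})

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf(
    "GaussianFit: center (%.2f, %.2f) px, sigma (%.3f, %.3f) px\n",
    object@center[1], object@center[2], object@sigma[1], object@sigma[2]))
})
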