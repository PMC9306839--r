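## Synthetic vessel phantom, parametric PSF rasterization, and simulated
## blurred + noisy view measurements.

## run expr with a local, restored RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic vessel-like phantom
#'
#' Draws \code{structureCount} smooth curvilinear tubes (seeded
#' bounded-curvature random-walk centerlines, dilated to the requested
#' width and lightly Gaussian-smoothed) on a zero background, then
#' normalizes the peak to \code{intensityMax}.  Vessels are kept away from
#' a border margin, so the raster corners are guaranteed sample-free and
#' can serve as background regions for SNR estimation.  The result is a
#' deterministic function of \code{spec} (including its seed).
#'
#' @param spec a [PhantomSpec-class].
#' @return nonnegative numeric matrix of extents \code{spec@shape}.
#' @examples
#' ph <- makeVesselPhantom(PhantomSpec(shape = c(95, 95), seed = 1))
#' dim(ph)
#' @export
makeVesselPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@shape
  canvas <- matrix(0, d[1], d[2])
  if (spec@structureCount == 0L) {
    warning("structureCount is 0: returning an all-zero raster")
    return(canvas)
  }
  margin <- 18
  lo <- margin + 1
  hi <- d - margin
  .withSeed(spec@seed, {
    for (v in seq_len(spec@structureCount)) {
      amp <- runif(1, 0.45, 1)
      w <- runif(1, spec@vesselWidthRange[1], spec@vesselWidthRange[2])
      r <- w / 2
      p <- c(runif(1, lo, hi[1]), runif(1, lo, hi[2]))
      phi <- runif(1, 0, 2 * pi)
      nSteps <- sample(60:220, 1)
      rad <- ceiling(r + 0.5)
      for (s in seq_len(nSteps)) {
        ir <- round(max(1 + rad, min(d[1] - rad, p[1])))
        ic <- round(max(1 + rad, min(d[2] - rad, p[2])))
        ii <- (ir - rad):(ir + rad)
        jj <- (ic - rad):(ic + rad)
        dist2 <- outer((ii - p[1])^2, (jj - p[2])^2, "+")
        patch <- canvas[ii, jj]
        hit <- dist2 <= r^2
        patch[hit] <- pmax(patch[hit], amp)
        canvas[ii, jj] <- patch
        phi <- phi + rnorm(1, 0, 0.12)
        p <- p + c(cos(phi), sin(phi))
        if (p[1] < lo || p[1] > hi[1] || p[2] < lo || p[2] > hi[2]) break
      }
    }
  })
  smooth <- rasterizePsf(PsfModel(0.8, 0.8, 0, d))
  canvas <- fftConvolve(canvas, smooth)
  canvas[canvas < 0] <- 0
  canvas / max(canvas) * spec@intensityMax
}

#' Rasterize an anisotropic Gaussian PSF
#'
#' Evaluates the Gaussian of a [PsfModel-class] on its pixel grid, rotated
#' by \code{theta} about the central pixel, and normalizes the raster to
#' unit sum.  Odd extents are required so that the rotation axis is a
#' pixel center and the raster is point-symmetric at \code{theta = 0}.
#'
#' @param model a [PsfModel-class].
#' @return nonnegative unit-sum numeric matrix.
#' @examples
#' h <- rasterizePsf(PsfModel(2.7, 1, 0, c(31, 31)))
#' sum(h)
#' @export
rasterizePsf <- function(model) {
  stopifnot(is(model, "PsfModel"))
  validObject(model)
  d <- model@shape
  ctr <- centerIndex(d)
  dz <- seq_len(d[1]) - ctr[1]
  dx <- seq_len(d[2]) - ctr[2]
  th <- model@theta * pi / 180
  ## rotated frame: u along the axial (sigmaAxial) direction
  u <- outer(cos(th) * dz, sin(th) * dx, "+")
  v <- outer(-sin(th) * dz, cos(th) * dx, "+")
  w <- exp(-u^2 / (2 * model@sigmaAxial^2) -
             v^2 / (2 * model@sigmaLateral^2))
  w / sum(w)
}

#' Simulate one blurred, noisy view
#'
#' Implements the per-view measurement model: the object is convolved with
#' the (rasterized) PSF, rescaled so its maximum equals
#' \code{intensityMax}, and corrupted with Poisson noise of parameter
#' \code{noiseMean}.
#'
#' Two noise models are supported.  \code{"scaled-poisson"} (the study
#' default) treats the rescaled image as carrying \code{noiseMean} photons
#' at its peak: \code{f = (intensityMax/noiseMean) *
#' rpois(s * noiseMean / intensityMax)}, so the peak has mean
#' \code{intensityMax} and variance governed by \eqn{\lambda =}
#' \code{noiseMean}, while zero-signal pixels remain exactly zero.
#' \code{"additive"} adds an independent Poisson(\code{noiseMean}) count
#' to every pixel.  See the methods vignette for the rationale.
#'
#' @param object nonnegative numeric matrix (the ground-truth raster).
#' @param psf a [PsfModel-class] or a nonnegative kernel matrix of the
#'   same shape as \code{object} (normalized to unit sum internally).
#' @param noiseMean Poisson parameter \eqn{\lambda} (counts); 0 disables
#'   noise.
#' @param seed integer seed for the noise realization.
#' @param intensityMax normalization ceiling (counts).
#' @param noiseModel \code{"scaled-poisson"} or \code{"additive"}.
#' @return nonnegative numeric matrix, same shape as \code{object}.
#' @examples
#' obj <- matrix(0, 31, 31); obj[10:20, 16] <- 1
#' v <- simulateView(obj, PsfModel(2.7, 1, 0, c(31, 31)), seed = 1)
#' @export
simulateView <- function(object, psf, noiseMean = 2^8, seed = 0L,
                         intensityMax = 2^16,
                         noiseModel = c("scaled-poisson", "additive")) {
  noiseModel <- match.arg(noiseModel)
  .checkRaster(object)
  if (min(object) < 0) stop("object raster must be nonnegative")
  if (!is.finite(noiseMean) || noiseMean < 0)
    stop("noiseMean must be a nonnegative number")
  kernel <- if (is(psf, "PsfModel")) rasterizePsf(psf) else psf
  .checkRaster(kernel, "psf")
  .checkSameShape(object, kernel)
  if (min(kernel) < 0) stop("psf raster must be nonnegative")
  kernel <- kernel / sum(kernel)
  blurred <- fftConvolve(object, kernel)
  blurred[blurred < 0] <- 0
  if (max(blurred) <= 0) stop("blurred object has no signal to normalize")
  s <- blurred / max(blurred) * intensityMax
  if (noiseMean == 0) return(s)
  .withSeed(seed, {
    if (noiseModel == "additive") {
      s + rpois(length(s), noiseMean)
    } else {
      scale <- intensityMax / noiseMean
      matrix(scale * rpois(length(s), s / scale), nrow(s), ncol(s))
    }
  })
}
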