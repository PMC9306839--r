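## Iterative solvers: Richardson-Lucy deconvolution, anchor-update (AU)
## autocorrelation inversion, and the alternating Blind-AU scheme.
##
## Single-step functions are pure R (readable, and the oracle cross-check
## surface); the multi-iteration drivers call the FFTW-backed C++ core,
## which implements exactly the same updates.

## shared multiplicative update: x * [ (data / (x * kernel)) .conv. rev(kernel) ]
.multiplicativeStep <- function(x, data, kernel, epsRel = 1e-12) {
  denom <- fftConvolve(x, kernel)
  floorv <- max(epsRel * max(denom), 1e-300)
  ratio <- data / pmax(denom, floorv)
  upd <- fftConvolve(ratio, reverseRaster(kernel))
  pmax(x * upd, 0)
}

#' One Richardson-Lucy update
#'
#' \eqn{o_{t+1} = o_t \cdot [ (f_\mu / (o_t * h)) * \tilde h ]} with a
#' unit-sum kernel \code{h}.  Nonnegativity is preserved, and with cyclic
#' boundaries the update conserves total flux when
#' \eqn{f_\mu = o_t * h} exactly.  Denominator pixels are floored at
#' \code{epsRel * max(denominator)}.
#'
#' @param o current object estimate (nonnegative matrix).
#' @param f blurred measurement, same shape.
#' @param h unit-sum PSF raster, same shape.
#' @param epsRel relative floor for the denominator.
#' @return updated object estimate.
#' @export
rlStep <- function(o, f, h, epsRel = 1e-12) {
  .checkRaster(o); .checkRaster(f); .checkRaster(h)
  .checkSameShape(o, f); .checkSameShape(o, h)
  .multiplicativeStep(o, f, h, epsRel)
}

#' Richardson-Lucy deconvolution
#'
#' Runs \code{nIter} Richardson-Lucy updates of the object estimate
#' against measurement \code{f} with fixed kernel \code{h}.  The default
#' initial guess is the measurement itself with zeros floored.
#'
#' @param f blurred measurement (nonnegative matrix).
#' @param h PSF: a [PsfModel-class] or a nonnegative raster of the same
#'   shape as \code{f} (normalized to unit sum internally).
#' @param nIter number of iterations (>= 1).
#' @param o0 initial guess; \code{NULL} (default) uses
#'   \code{floorZeros(f)}.  Must be nonnegative.
#' @param epsRel relative denominator floor.
#' @param recordMSE if \code{TRUE}, also return the per-iteration
#'   energy-normalized MSE between \eqn{o_t * h} and \code{f}.
#' @return list with \code{estimate} (matrix) and \code{mseTrace}
#'   (numeric vector, empty unless \code{recordMSE}).
#' @export
rlDeconvolve <- function(f, h, nIter, o0 = NULL, epsRel = 1e-12,
                         recordMSE = TRUE) {
  .checkRaster(f)
  kernel <- if (is(h, "PsfModel")) rasterizePsf(h) else h
  .checkRaster(kernel, "h"); .checkSameShape(f, kernel)
  if (min(kernel) < 0) stop("kernel must be nonnegative")
  kernel <- kernel / sum(kernel)
  if (nIter < 1) stop("nIter must be >= 1")
  if (is.null(o0)) o0 <- floorZeros(pmax(f, 0))
  .checkRaster(o0, "o0"); .checkSameShape(f, o0)
  if (min(o0) < 0) stop("initial guess o0 must be nonnegative")
  res <- cpp_rl_run(f, kernel, o0, as.integer(nIter), epsRel, recordMSE)
  list(estimate = res$estimate, mseTrace = as.numeric(res$mse_trace))
}

#' Effective AU kernel
#'
#' \eqn{K = x \star A} (cross-correlation of the current estimate with the
#' fixed autocorrelation field), normalized to unit sum so the
#' multiplicative AU update keeps the Richardson-Lucy fixed-point
#' structure.
#'
#' @param current current estimate (nonnegative matrix).
#' @param fixedAutocorr autocorrelation raster of the fixed element
#'   (e.g. \eqn{H = h \star h}), same shape.
#' @return unit-sum kernel matrix.
#' @export
auKernel <- function(current, fixedAutocorr) {
  .checkRaster(current); .checkRaster(fixedAutocorr)
  .checkSameShape(current, fixedAutocorr)
  K <- fftCorrelate(current, fixedAutocorr)
  s <- sum(K)
  if (s <= 0) stop("effective kernel is all-zero; cannot normalize")
  K / s
}

#' One anchor-update iteration
#'
#' \eqn{o_{t+1} = o_t \cdot [ (\chi_\mu / (o_t * K_t)) * \tilde K_t ]}:
#' the Richardson-Lucy-shaped multiplicative update acting in
#' autocorrelation space, with the unit-sum effective kernel \eqn{K_t}
#' (see [auKernel()]).
#'
#' @param o current estimate (nonnegative matrix).
#' @param chi averaged autocorrelation (the data), same shape.
#' @param K unit-sum effective kernel, same shape.
#' @param epsRel relative denominator floor.
#' @return updated estimate.
#' @export
auStep <- function(o, chi, K, epsRel = 1e-12) {
  .checkRaster(o); .checkRaster(chi); .checkRaster(K)
  .checkSameShape(o, chi); .checkSameShape(o, K)
  .multiplicativeStep(o, chi, K, epsRel)
}

#' Anchor-update inversion with a known PSF
#'
#' Inverts \eqn{\chi_\mu = o \star o * H} for the object, iterating
#' [auKernel()] + [auStep()] with the PSF autocorrelation
#' \eqn{H = |h \star h|} held fixed.
#'
#' @param chi averaged autocorrelation raster.
#' @param psf a [PsfModel-class] or PSF raster of the same shape.
#' @param o0 strictly positive initial object guess.
#' @param nIter number of AU iterations.
#' @param epsRel relative denominator floor.
#' @param recordResidual if \code{TRUE}, record the energy-normalized
#'   autocorrelation residual
#'   \eqn{\| \widehat{o \star o * H} - \hat\chi_\mu \|_2} (both fields
#'   scaled to unit L2 norm) before each iteration; normalization because
#'   the unit-sum kernel convention fixes the estimate's flux to
#'   \code{sum(chi)} rather than to the data scale.
#' @return list with \code{estimate} and \code{residualTrace}.
#' @export
auDeconvolve <- function(chi, psf, o0, nIter, epsRel = 1e-12,
                         recordResidual = FALSE) {
  .checkRaster(chi)
  kernel <- if (is(psf, "PsfModel")) rasterizePsf(psf) else psf
  .checkRaster(kernel, "psf"); .checkSameShape(chi, kernel)
  .checkRaster(o0, "o0"); .checkSameShape(chi, o0)
  if (min(o0) < 0) stop("initial guess o0 must be nonnegative")
  if (nIter < 1) stop("nIter must be >= 1")
  H <- abs(autocorrelate(kernel))
  res <- cpp_au_run(chi, H, o0, as.integer(nIter), epsRel, recordResidual)
  list(estimate = res$estimate,
       residualTrace = as.numeric(res$residual_trace))
}

#' Blind-AU: alternating object / PSF autocorrelation inversion
#'
#' Runs \code{cycles} outer alternations.  In the object block the PSF is
#' fixed through its absolute autocorrelation \eqn{H_{k-1}} and the object
#' receives \code{objectIters} AU updates with kernel
#' \eqn{K = o \star H_{k-1}}; in the PSF block the roles swap
#' (\eqn{K' = h \star O_k} with \eqn{O_k = |o_k \star o_k|}) for
#' \code{psfIters} updates.  The PSF is renormalized to unit sum at each
#' block boundary; the object scale is left free (it is fixed by
#' \eqn{\chi_\mu}).
#'
#' Checkpoints are recorded every \code{checkpointEvery} cycles: object
#' flux, PSF second-moment standard deviations along the principal axes,
#' and, when \code{measurement} is given, the energy-normalized MSE
#' between the re-blurred object and the measurement plus the object SNR
#' over \code{background}.
#'
#' @param chi averaged absolute autocorrelation \eqn{\chi_\mu}.
#' @param o0 strictly positive initial object guess (typically the fused
#'   aligned average after [floorZeros()]).
#' @param h0 initial PSF guess: a [PsfModel-class], a raster, or
#'   \code{"random"} for a strictly positive uniform draw (seeded by
#'   \code{seed}).  The default is the isotropic Gaussian with
#'   \eqn{\sigma = 4} px.
#' @param schedule a [BlindSchedule-class].
#' @param epsRel relative denominator floor.
#' @param measurement optional fused measurement raster for MSE/SNR
#'   checkpoints.
#' @param background logical mask (or corner-patch size, see
#'   [cornerBackgroundMask()]) for checkpoint SNR; default 15-px corners.
#' @param seed seed used when \code{h0 = "random"}.
#' @return a [ReconstructionState-class].
#' @export
blindAU <- function(chi, o0, h0 = NULL, schedule = BlindSchedule(),
                    epsRel = 1e-12, measurement = NULL, background = 15L,
                    seed = 0L) {
  .checkRaster(chi)
  stopifnot(is(schedule, "BlindSchedule"))
  validObject(schedule)
  .checkRaster(o0, "o0"); .checkSameShape(chi, o0)
  if (min(o0) <= 0)
    stop("o0 must be strictly positive; apply floorZeros() first")
  if (is.null(h0)) h0 <- PsfModel(4, 4, 0, dim(chi))
  if (identical(h0, "random")) {
    h0 <- .withSeed(seed, matrix(runif(length(chi), min = 1e-3, max = 1),
                                 nrow(chi), ncol(chi)))
  } else if (is(h0, "PsfModel")) h0 <- rasterizePsf(h0)
  .checkRaster(h0, "h0"); .checkSameShape(chi, h0)
  if (min(h0) <= 0 || sum(h0) <= 0)
    stop("h0 must be strictly positive")
  h0 <- h0 / sum(h0)
  mask <- if (is.null(measurement)) NULL
          else if (is.matrix(background)) background
          else cornerBackgroundMask(dim(chi),
                 min(as.integer(background), min(dim(chi)) %/% 4L))

  o <- o0; h <- h0
  done <- 0L
  hist <- list()
  while (done < schedule@cycles) {
    chunk <- min(schedule@checkpointEvery, schedule@cycles - done)
    res <- cpp_blind_run(chi, o, h, schedule@objectIters,
                         schedule@psfIters, as.integer(chunk), epsRel)
    o <- res$object; h <- res$psf
    done <- done + chunk
    mom <- psfSecondMoments(h)
    row <- data.frame(cycle = done, objectFlux = sum(o),
                      psfSigmaMajor = sqrt(max(mom$eigenvalues)),
                      psfSigmaMinor = sqrt(max(0, min(mom$eigenvalues))))
    if (!is.null(measurement)) {
      row$mse <- imageMSE(o, h, measurement)
      row$snrDb <- imageSNR(o, mask)
    }
    hist[[length(hist) + 1L]] <- row
  }
  new("ReconstructionState", objectEstimate = o, psfEstimate = h,
      chi = chi, cycle = done, history = do.call(rbind, hist))
}
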