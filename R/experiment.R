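## End-to-end synthetic multiview study: phantom -> blurred noisy views ->
## averaged autocorrelation -> Blind-AU, with a known-PSF Richardson-Lucy
## comparison arm and quality metrics.

#' Simulate a misaligned multiview measurement of a phantom
#'
#' Generates one blurred, noisy view per angle in \code{spec@angles}
#' (rotating the true PSF accordingly), then applies a random rigid
#' integer shift (up to \code{spec@maxViewShift} px per axis, seeded) to
#' every non-reference view, mimicking an uncalibrated acquisition.
#'
#' @param truth ground-truth raster (e.g. from [makeVesselPhantom()]).
#' @param spec a [PhantomSpec-class] (noise, angles, seed).
#' @param psfSigma true PSF standard deviations (axial, lateral), px.
#' @return list with \code{views} (a [ViewSet-class]), \code{psfs} (list
#'   of [PsfModel-class]), \code{truePsfAverage} (unit-sum raster) and
#'   \code{shifts} (applied misalignments, m x 2).
#' @export
simulateViewSet <- function(truth, spec, psfSigma = c(2.7, 1)) {
  stopifnot(is(spec, "PhantomSpec"))
  .checkRaster(truth)
  m <- length(spec@angles)
  psfs <- lapply(spec@angles, function(a)
    PsfModel(psfSigma[1], psfSigma[2], a, dim(truth)))
  views <- vector("list", m)
  for (i in seq_len(m))
    views[[i]] <- simulateView(truth, psfs[[i]], spec@noiseMean,
                               seed = spec@seed + i,
                               intensityMax = spec@intensityMax,
                               noiseModel = spec@noiseModel)
  shifts <- matrix(0L, m, 2)
  if (m > 1 && spec@maxViewShift > 0) {
    rng <- -spec@maxViewShift:spec@maxViewShift
    shifts[-1, ] <- .withSeed(spec@seed + 10000L,
                              matrix(sample(rng, 2L * (m - 1L),
                                            replace = TRUE), m - 1L, 2))
    for (i in seq_len(m)[-1])
      views[[i]] <- applyShift(views[[i]], shifts[i, ])
  }
  hbar <- Reduce(`+`, lapply(psfs, rasterizePsf)) / m
  list(views = ViewSet(views, spec@angles), psfs = psfs,
       truePsfAverage = hbar, shifts = shifts)
}

#' Run the full synthetic blind-deconvolution experiment
#'
#' Executes the whole pipeline: vessel phantom, simulated misaligned
#' views, averaged absolute autocorrelation \eqn{\chi_\mu},
#' cross-correlation alignment and fusion into the initial guess,
#' Blind-AU reconstruction, a Richardson-Lucy arm deconvolving the fused
#' measurement with the exact (averaged) blurring PSF, and the quality
#' metrics of all three images.  Deterministic given the config seed.
#'
#' @param config an [ExperimentConfig-class].
#' @return a list of class \code{"blindAUExperiment"} with components
#'   \code{truth}, \code{measurement} (the raw [ViewSet-class]),
#'   \code{appliedShifts}, \code{detectedShifts}, \code{chi},
#'   \code{fused} (floored aligned average), \code{truePsfAverage},
#'   \code{blind} (a [ReconstructionState-class]), \code{rl} (estimate +
#'   MSE trace), \code{metrics} (data.frame) and \code{config}.
#' @export
runSyntheticExperiment <- function(config = experimentConfig()) {
  stopifnot(is(config, "ExperimentConfig"))
  validObject(config)
  spec <- config@phantom
  truth <- makeVesselPhantom(spec)
  sim <- simulateViewSet(truth, spec, config@psfSigma)

  chi <- averageAutocorrelation(sim$views)
  al <- alignViews(sim$views)
  fused <- floorZeros(fuseAligned(al$views))
  mask <- cornerBackgroundMask(dim(fused), config@backgroundSize)

  h0 <- switch(config@initialPsf$type,
    gaussian = PsfModel(config@initialPsf$sigma, config@initialPsf$sigma,
                        0, dim(fused)),
    random = "random",
    file = readRaster(config@initialPsf$path))
  blind <- blindAU(chi, o0 = fused, h0 = h0, schedule = config@schedule,
                   measurement = fused, background = mask,
                   seed = if (is.null(config@initialPsf$seed)) spec@seed
                          else config@initialPsf$seed)

  rl <- rlDeconvolve(fused, sim$truePsfAverage,
                     nIter = config@rlIterations, o0 = fused)

  metrics <- data.frame(
    image = c("measurement", "blindAU", "RLD"),
    snrDb = c(imageSNR(fused, mask),
              imageSNR(objectEstimate(blind), mask),
              imageSNR(rl$estimate, mask)),
    mse = c(NA,
            imageMSE(objectEstimate(blind), psfEstimate(blind), fused),
            imageMSE(rl$estimate, sim$truePsfAverage, fused)))

  report <- structure(list(truth = truth, measurement = sim$views,
                           appliedShifts = sim$shifts,
                           detectedShifts = al$shifts, chi = chi,
                           fused = fused,
                           truePsfAverage = sim$truePsfAverage,
                           blind = blind, rl = rl, metrics = metrics,
                           config = config),
                      class = "blindAUExperiment")
  if (nzchar(config@outputDir)) .writeExperimentOutputs(report)
  report
}

.writeExperimentOutputs <- function(report) {
  dir <- report$config@outputDir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeRaster(report$truth, file.path(dir, "ground_truth.tif"))
  for (i in seq_along(viewRasters(report$measurement)))
    writeRaster(viewRasters(report$measurement)[[i]],
                file.path(dir, sprintf("view_%02d.tif", i)))
  writeRaster(report$chi, file.path(dir, "chi.tif"))
  writeRaster(report$fused, file.path(dir, "fused_guess.tif"))
  writeRaster(objectEstimate(report$blind),
              file.path(dir, "blind_object.tif"))
  writeRaster(psfEstimate(report$blind), file.path(dir, "blind_psf.tif"))
  writeRaster(report$rl$estimate, file.path(dir, "rld_object.tif"))
  writeRaster(report$truePsfAverage, file.path(dir, "true_psf_average.tif"))
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(convergenceHistory(report$blind),
                   file.path(dir, "blind_history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @export
print.blindAUExperiment <- function(x, ...) {
  cat("Synthetic multiview blind-deconvolution experiment\n")
  print(x$config@phantom)
  print(x$config@schedule)
  cat(sprintf("  applied view shifts:  %s\n",
              paste(apply(x$appliedShifts, 1, paste, collapse = ","),
                    collapse = "  ")))
  cat(sprintf("  detected view shifts: %s\n",
              paste(apply(x$detectedShifts, 1, paste, collapse = ","),
                    collapse = "  ")))
  cat("metrics:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
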