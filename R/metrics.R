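## Quality metrics and Gaussian PSF characterization.

#' Energy-normalized mean squared error
#'
#' \eqn{\mathrm{MSE} = \sum_x (\widehat{o*h}(x) - \hat s_\mu(x))^2} where
#' both the re-blurred reconstruction \eqn{o_{rec} * h} and the
#' measurement \eqn{s_\mu} are first divided by their L2 norm
#' ("energy-normalized"), making the metric invariant to positive
#' rescaling of either argument.
#'
#' @param oRec reconstructed object raster.
#' @param h PSF raster or [PsfModel-class] (unit-sum normalized
#'   internally).
#' @param sMu measurement raster, same shape.
#' @return nonnegative scalar (a.u.; 2 for orthogonal unit-energy images).
#' @examples
#' a <- matrix(runif(25), 5); d <- matrix(0, 5, 5); d[3, 3] <- 1
#' imageMSE(a, d, 3 * a)  # scale-free: 0
#' @export
imageMSE <- function(oRec, h, sMu) {
  .checkRaster(oRec); .checkRaster(sMu); .checkSameShape(oRec, sMu)
  kernel <- if (is(h, "PsfModel")) rasterizePsf(h) else h
  .checkRaster(kernel, "h"); .checkSameShape(oRec, kernel)
  kernel <- kernel / sum(kernel)
  blurred <- fftConvolve(oRec, kernel)
  eb <- sqrt(sum(blurred^2)); es <- sqrt(sum(sMu^2))
  if (eb == 0 || es == 0) stop("zero-energy input; MSE undefined")
  sum((blurred / eb - sMu / es)^2)
}

#' Logical mask selecting the four corner patches of a raster
#'
#' The synthetic phantom keeps a vessel-free margin, so the raster corners
#' are guaranteed sample-free background for SNR estimation.
#'
#' @param dim raster extents.
#' @param size patch side length in pixels.
#' @return logical matrix, \code{TRUE} on the four size x size corners.
#' @export
cornerBackgroundMask <- function(dim, size = 15L) {
  size <- as.integer(size)
  stopifnot(size >= 1, all(dim >= 2L * size))
  m <- matrix(FALSE, dim[1], dim[2])
  ii <- c(seq_len(size), dim[1] - seq_len(size) + 1L)
  jj <- c(seq_len(size), dim[2] - seq_len(size) + 1L)
  m[ii, jj] <- TRUE
  m
}

#' Peak-over-background signal-to-noise ratio
#'
#' \eqn{\mathrm{SNR} = 20 \log_{10}(s_{max}/\epsilon)} in dB, where
#' \eqn{s_{max}} is the peak intensity and \eqn{\epsilon} the mean over a
#' sample-free background region.  Invariant to positive rescaling of the
#' whole image.
#'
#' @param image numeric matrix.
#' @param background logical mask of the background region (same shape),
#'   or a corner-patch size passed to [cornerBackgroundMask()].
#' @return SNR in dB.
#' @examples
#' img <- matrix(10, 60, 60); img[30, 30] <- 1000
#' imageSNR(img, 15)  # 20*log10(100) = 40 dB
#' @export
imageSNR <- function(image, background = 15L) {
  .checkRaster(image)
  mask <- if (is.matrix(background)) background else
    cornerBackgroundMask(dim(image), as.integer(background))
  if (!is.logical(mask)) stop("background mask must be logical")
  if (!identical(dim(mask), dim(image)))
    stop("background mask and image must share one shape")
  if (!any(mask)) stop("background region is empty")
  eps <- mean(image[mask])
  if (eps <= 0) stop("background mean must be positive for SNR")
  20 * log10(max(image) / eps)
}

## 1D Gaussian + offset least-squares fit of one profile.  Direct
## Nelder-Mead minimization of the SSE (moment-based starting values);
## unlike a gradient solver it also handles exactly-Gaussian input, where
## the zero-residual point makes the nls gradient singular.
.fitGaussian1D <- function(y) {
  x <- seq_along(y)
  off0 <- min(y)
  amp0 <- max(y) - off0
  if (amp0 <= 0) stop("fit did not converge: flat profile")
  c0 <- which.max(y)
  w <- pmax(y - off0, 0)
  s0 <- max(sqrt(sum(w * (x - c0)^2) / sum(w)), 0.5)
  sse <- function(p)
    sum((p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)) + p[4] - y)^2)
  fit <- stats::optim(c(amp0, c0, s0, off0), sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  p <- fit$par
  if (fit$convergence != 0 || abs(p[3]) <= 1e-3 || p[1] <= 0)
    stop("fit did not converge: degenerate Gaussian parameters")
  list(center = p[2], sigma = abs(p[3]), amplitude = p[1], offset = p[4],
       residual = sqrt(fit$value / length(y)))
}

#' Axis-wise Gaussian fit of a PSF-like blob
#'
#' Locates the dominant maximum and least-squares fits a 1D Gaussian plus
#' constant offset to the row and column profiles through it (one fit per
#' axis), mirroring how bead images are reduced to an analytic PSF.
#'
#' @param beadImage raster containing a single dominant blob.
#' @return a [GaussianFit-class] with per-axis (row, column) center,
#'   sigma, amplitude, offset and residual standard error.
#' @examples
#' h <- rasterizePsf(PsfModel(2.7, 1, 0, c(41, 41)))
#' psfSigma(fitGaussianPsf(h))
#' @export
fitGaussianPsf <- function(beadImage) {
  .checkRaster(beadImage)
  if (diff(range(beadImage)) == 0)
    stop("fit did not converge: flat image has no blob")
  pk <- arrayInd(which.max(beadImage), dim(beadImage))
  fr <- .fitGaussian1D(beadImage[, pk[2]])
  fc <- .fitGaussian1D(beadImage[pk[1], ])
  new("GaussianFit",
      center = c(fr$center, fc$center),
      sigma = c(fr$sigma, fc$sigma),
      amplitude = c(fr$amplitude, fc$amplitude),
      offset = c(fr$offset, fc$offset),
      residual = c(fr$residual, fc$residual))
}

#' Second moments and principal axes of an intensity distribution
#'
#' Treats the raster as a 2D mass distribution: returns the intensity
#' centroid, the 2 x 2 second-moment (covariance) matrix about it, its
#' eigenvalues (variances along the principal axes, px^2) and the
#' orientation of the major axis.
#'
#' @param x nonnegative raster (e.g. a PSF estimate).
#' @return list with \code{centroid}, \code{cov}, \code{eigenvalues} and
#'   \code{angle} (major-axis angle in degrees from the row axis, in
#'   (-90, 90]).
#' @export
psfSecondMoments <- function(x) {
  .checkRaster(x)
  w <- pmax(x, 0)
  s <- sum(w)
  if (s <= 0) stop("cannot compute moments of a nonpositive raster")
  d <- dim(x)
  ri <- row(x); ci <- col(x)
  mr <- sum(w * ri) / s; mc <- sum(w * ci) / s
  crr <- sum(w * (ri - mr)^2) / s
  ccc <- sum(w * (ci - mc)^2) / s
  crc <- sum(w * (ri - mr) * (ci - mc)) / s
  cv <- matrix(c(crr, crc, crc, ccc), 2, 2)
  ev <- eigen(cv, symmetric = TRUE)
  ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  list(centroid = c(mr, mc), cov = cv, eigenvalues = ev$values,
       angle = ang)
}

#' Orientation of a four-fold-symmetric (cross-shaped) kernel
#'
#' The principal axes of the second-moment tensor are undefined for a
#' perfectly symmetric cross (the tensor is isotropic), so the closer a
#' star-shaped PSF estimate gets to the truth, the noisier its
#' second-moment angle becomes.  This measure stays well conditioned: it
#' is the phase of the fourth angular harmonic of the intensity
#' distribution about its centroid,
#' \eqn{\theta = \frac{1}{4}\arg \sum_x w(x)\, r(x)^2 e^{4 i \phi(x)}},
#' which for a cross with arms along the row/column axes is 0 regardless
#' of how symmetric the arms are.
#'
#' @param x nonnegative raster (e.g. a PSF estimate).
#' @return arm orientation in degrees, in \code{(-45, 45]} (the measure
#'   is 90-degree periodic); 0 means arms along the raster axes.
#' @export
crossOrientation <- function(x) {
  .checkRaster(x)
  w <- pmax(x, 0)
  if (sum(w) <= 0) stop("cannot orient a nonpositive raster")
  mr <- sum(w * row(x)) / sum(w)
  mc <- sum(w * col(x)) / sum(w)
  ri <- row(x) - mr; ci <- col(x) - mc
  z <- sum(w * (ri^2 + ci^2) * exp(4i * atan2(ci, ri)))
  Arg(z) / 4 * 180 / pi   # (-45, 45]; 0 = arms along the raster axes
}

#' Normalized cross-correlation after registering trivial ambiguities
#'
#' Autocorrelation determines a raster only up to cyclic translation and
#' point reflection.  This registers both: it maximizes the cosine
#' similarity \eqn{\langle a, b \rangle / (\|a\| \|b\|)} over all cyclic
#' shifts of \code{b} and over its point reflection.
#'
#' @param a,b nonnegative rasters of identical shape.
#' @return list with \code{ncc} (best similarity in [0, 1] for nonnegative
#'   inputs), \code{shift} (the maximizing shift of \code{b}) and
#'   \code{flipped} (whether the reflection won).
#' @export
registeredNCC <- function(a, b) {
  .checkRaster(a); .checkRaster(b); .checkSameShape(a, b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-energy input")
  best <- function(bb) {
    cc <- fftCorrelate(a, bb)
    idx <- arrayInd(which.max(cc), dim(cc))
    list(v = max(cc) / (na * nb), shift = as.integer(idx - centerIndex(dim(cc))))
  }
  s1 <- best(b); s2 <- best(reverseRaster(b))
  if (s1$v >= s2$v)
    list(ncc = s1$v, shift = s1$shift, flipped = FALSE)
  else
    list(ncc = s2$v, shift = s2$shift, flipped = TRUE)
}
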