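## Fourier-domain convolution / correlation primitives.
##
## Conventions (fixed once, used by every solver):
##   * a raster is a numeric matrix; its zero-shift origin is the center
##     pixel floor(dim/2) + 1 (1-based) per axis;
##   * correlation is (f .corr. g)(x) = sum_y f(y) g(y + x), computed as the
##     inverse transform of Conj(F f) * F g;
##   * convolution is cyclic by default ("circular"); "linear" embeds both
##     rasters in a 2N-1 zero-padded frame, so no wrap-around occurs, and
##     crops back around the center.

.checkRaster <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  invisible(x)
}

.checkSameShape <- function(f, g) {
  if (!identical(dim(f), dim(g)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(f), collapse = "x"),
                 paste(dim(g), collapse = "x")), call. = FALSE)
  invisible(NULL)
}

#' Center pixel of a raster
#'
#' The designated zero-shift origin: \code{floor(extent/2) + 1} per axis
#' (the central pixel for odd extents).
#'
#' @param dim integer extents (e.g. \code{dim(x)}).
#' @return integer vector of 1-based center indices.
#' @examples
#' centerIndex(c(191, 191))  # c(96, 96)
#' @export
centerIndex <- function(dim) as.integer(dim %/% 2L + 1L)

#' Cyclic shift of a raster
#'
#' Moves content by \code{shift} pixels per axis with wrap-around:
#' \code{out[i, j] = x[i - shift[1], j - shift[2]]} (cyclically).
#'
#' @param x numeric matrix.
#' @param shift integer shift per axis.
#' @return shifted matrix.
#' @export
circShift <- function(x, shift) {
  .checkRaster(x)
  d <- dim(x)
  s <- as.integer(round(shift)) %% d
  i <- ((seq_len(d[1]) - 1L - s[1]) %% d[1]) + 1L
  j <- ((seq_len(d[2]) - 1L - s[2]) %% d[2]) + 1L
  x[i, j, drop = FALSE]
}

## embed f centered in a (2n-1) frame; returns list(pad, crop indices)
.padFrame <- function(d) 2L * d - 1L

.embedCentered <- function(x, pd) {
  d <- dim(x)
  out <- matrix(0, pd[1], pd[2])
  off <- centerIndex(pd) - centerIndex(d)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- x
  out
}

.cropCentered <- function(x, d) {
  off <- centerIndex(dim(x)) - centerIndex(d)
  x[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), drop = FALSE]
}

.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

.convolveCircular <- function(f, g) {
  raw <- Re(.ifft2(.fft2(f) * .fft2(g)))
  circShift(raw, -(dim(f) %/% 2L))
}

.correlateCircular <- function(f, g) {
  raw <- Re(.ifft2(Conj(.fft2(f)) * .fft2(g)))
  circShift(raw, dim(f) %/% 2L)
}

#' Fourier-domain convolution with centered kernels
#'
#' Computes \code{f * g} so that a unit impulse at the center pixel is the
#' identity element.  \code{pad = "circular"} (default) is the cyclic
#' convolution used throughout the solvers; \code{pad = "linear"} zero-pads
#' to \code{2N - 1} per axis before transforming, suppressing wrap-around,
#' and crops the central region.
#'
#' @param f,g numeric matrices of identical shape.
#' @param pad boundary model, \code{"circular"} or \code{"linear"}.
#' @return numeric matrix, same shape as the inputs.
#' @examples
#' f <- matrix(runif(25), 5)
#' delta <- matrix(0, 5, 5); delta[3, 3] <- 1
#' stopifnot(all.equal(fftConvolve(f, delta), f))
#' @export
fftConvolve <- function(f, g, pad = c("circular", "linear")) {
  pad <- match.arg(pad)
  .checkRaster(f); .checkRaster(g); .checkSameShape(f, g)
  if (pad == "circular") return(.convolveCircular(f, g))
  pd <- .padFrame(dim(f))
  .cropCentered(.convolveCircular(.embedCentered(f, pd),
                                  .embedCentered(g, pd)), dim(f))
}

#' Fourier-domain cross-correlation
#'
#' Computes \code{(f .corr. g)(x) = sum_y f(y) g(y + x)} with the zero
#' shift mapped to the center pixel, so that
#' \code{fftCorrelate(f, g) == fftConvolve(reverseRaster(f), g)}.
#'
#' @inheritParams fftConvolve
#' @return numeric matrix of correlation values indexed by shift.
#' @examples
#' f <- matrix(runif(25), 5)
#' c0 <- centerIndex(dim(f))
#' stopifnot(all.equal(fftCorrelate(f, f)[c0[1], c0[2]], sum(f^2)))
#' @export
fftCorrelate <- function(f, g, pad = c("circular", "linear")) {
  pad <- match.arg(pad)
  .checkRaster(f); .checkRaster(g); .checkSameShape(f, g)
  if (pad == "circular") return(.correlateCircular(f, g))
  pd <- .padFrame(dim(f))
  .cropCentered(.correlateCircular(.embedCentered(f, pd),
                                   .embedCentered(g, pd)), dim(f))
}

#' Autocorrelation of a raster
#'
#' \code{fftCorrelate(f, f)}: point-symmetric about the center pixel, with
#' its global maximum (the total energy) at zero shift.  Invariant under
#' cyclic translation and under point reflection of the argument.
#'
#' @inheritParams fftConvolve
#' @param f numeric matrix.
#' @return numeric matrix of autocorrelation values indexed by shift.
#' @export
autocorrelate <- function(f, pad = c("circular", "linear")) {
  .checkRaster(f)
  fftCorrelate(f, f, pad = match.arg(pad))
}

#' Point reflection of a raster about its center pixel
#'
#' Cyclic coordinate reversal \eqn{\tilde f(x) = f(-x)} about the
#' zero-shift origin.  It is an involution, and
#' \code{fftCorrelate(f, g) == fftConvolve(reverseRaster(f), g)}.
#'
#' @param f numeric matrix.
#' @return reflected matrix.
#' @export
reverseRaster <- function(f) {
  .checkRaster(f)
  d <- dim(f)
  c0 <- d %/% 2L
  i <- ((2L * c0[1] - (seq_len(d[1]) - 1L)) %% d[1]) + 1L
  j <- ((2L * c0[2] - (seq_len(d[2]) - 1L)) %% d[2]) + 1L
  f[i, j, drop = FALSE]
}
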