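## Multiview preprocessing: background subtraction, quarter-turn rotation,
## cross-correlation registration, fusion by averaging, averaged absolute
## autocorrelation, and zero-flooring.

#' Subtract a dark (no-illumination) background stack
#'
#' Element-wise difference clamped at zero.
#'
#' @param view,dark numeric matrices of identical shape.
#' @return nonnegative numeric matrix.
#' @export
subtractBackground <- function(view, dark) {
  .checkRaster(view); .checkRaster(dark); .checkSameShape(view, dark)
  pmax(view - dark, 0)
}

#' Lossless quarter-turn rotation
#'
#' Rotates a raster by \code{quarterTurns} * 90 degrees counter-clockwise
#' by axis permutation and reflection; no interpolation is involved, and
#' four quarter turns are the identity.
#'
#' @param view numeric matrix.
#' @param quarterTurns integer number of 90-degree counter-clockwise turns
#'   (negative for clockwise).
#' @return rotated matrix.
#' @export
coarseRotate <- function(view, quarterTurns) {
  .checkRaster(view)
  q <- as.integer(quarterTurns) %% 4L
  if (q == 0L) return(view)
  for (k in seq_len(q)) view <- t(view)[rev(seq_len(ncol(view))), , drop = FALSE]
  view
}

#' Translational registration by cross-correlation peak
#'
#' Returns the integer shift at the arg-max of
#' \code{fftCorrelate(reference, moving)}, relative to zero shift.  If
#' \code{moving} equals \code{reference} cyclically shifted by \code{s},
#' the return value is \code{s}; applying \code{applyShift(moving, -s)}
#' compensates the misalignment.
#'
#' @param reference,moving numeric matrices of identical shape.
#' @return integer shift vector (rows, columns).
#' @export
registerTranslation <- function(reference, moving) {
  .checkRaster(reference); .checkRaster(moving)
  .checkSameShape(reference, moving)
  if (all(reference == 0) || all(moving == 0))
    stop("cross-correlation peak undefined for an all-zero raster")
  cc <- fftCorrelate(reference, moving)
  idx <- arrayInd(which.max(cc), dim(cc))
  as.integer(idx - centerIndex(dim(cc)))
}

#' Apply a rigid integer shift
#'
#' Moves content by \code{shift} pixels per axis.  With
#' \code{wrap = TRUE} (default) the shift is cyclic, losing no
#' information; with \code{wrap = FALSE} wrapped-in pixels are zeroed
#' (edge-crop behavior for truncated objects).
#'
#' @param x numeric matrix.
#' @param shift integer shift per axis (rows, columns).
#' @param wrap logical, cyclic (default) or zero-filled edges.
#' @return shifted matrix.
#' @export
applyShift <- function(x, shift, wrap = TRUE) {
  out <- circShift(x, shift)
  if (!wrap) {
    d <- dim(x)
    s <- as.integer(round(shift))
    if (abs(s[1]) >= d[1] || abs(s[2]) >= d[2]) return(matrix(0, d[1], d[2]))
    if (s[1] > 0) out[seq_len(s[1]), ] <- 0
    if (s[1] < 0) out[d[1] + seq(s[1] + 1, 0), ] <- 0
    if (s[2] > 0) out[, seq_len(s[2])] <- 0
    if (s[2] < 0) out[, d[2] + seq(s[2] + 1, 0)] <- 0
  }
  out
}

#' Align all views of a set against the reference view
#'
#' For each non-reference view, locates the cross-correlation peak against
#' the reference and compensates its opposite shift.
#'
#' @param views a [ViewSet-class].
#' @param wrap passed to [applyShift()].
#' @return a list with \code{views} (the aligned [ViewSet-class]) and
#'   \code{shifts} (an m x 2 integer matrix of detected shifts).
#' @export
alignViews <- function(views, wrap = TRUE) {
  stopifnot(is(views, "ViewSet"))
  validObject(views)
  ref <- views@views[[views@referenceIndex]]
  m <- length(views@views)
  shifts <- matrix(0L, m, 2)
  aligned <- views@views
  for (i in seq_len(m)) {
    if (i == views@referenceIndex) next
    s <- registerTranslation(ref, views@views[[i]])
    shifts[i, ] <- s
    aligned[[i]] <- applyShift(views@views[[i]], -s, wrap = wrap)
  }
  list(views = ViewSet(aligned, views@angles, views@referenceIndex),
       shifts = shifts)
}

#' Fuse aligned views by averaging
#'
#' Pixel-wise mean of the m views; the views are assumed registered (see
#' [alignViews()]).
#'
#' @param views a [ViewSet-class] or a nonempty list of rasters.
#' @return numeric matrix.
#' @export
fuseAligned <- function(views) {
  vs <- if (is(views, "ViewSet")) views@views else views
  if (length(vs) < 1) stop("cannot fuse an empty view set")
  Reduce(`+`, vs) / length(vs)
}

#' Averaged absolute autocorrelation of a view set
#'
#' The alignment-free fusion target \eqn{\chi_\mu}: the absolute value of
#' each view's autocorrelation (taken before averaging, to suppress tiny
#' negative round-off values) averaged over views.  Because
#' autocorrelation is invariant to cyclic translation, no alignment of the
#' views is required.
#'
#' @param views a [ViewSet-class] or a nonempty list of rasters.
#' @param pad boundary model passed to [autocorrelate()].
#' @return numeric matrix (point-symmetric about the center pixel).
#' @export
averageAutocorrelation <- function(views, pad = c("circular", "linear")) {
  pad <- match.arg(pad)
  vs <- if (is(views, "ViewSet")) views@views else views
  if (length(vs) < 1) stop("cannot average an empty view set")
  acs <- lapply(vs, function(v) abs(autocorrelate(v, pad = pad)))
  Reduce(`+`, acs) / length(acs)
}

#' Replace exact zeros by a small positive floor
#'
#' Sets every zero pixel to \code{mean(image)/100}.  Multiplicative
#' deconvolution updates can never lift an exactly-zero pixel, so initial
#' guesses are floored before iterating.
#'
#' @param image numeric matrix with at least one positive pixel.
#' @return numeric matrix with no zeros.
#' @export
floorZeros <- function(image) {
  .checkRaster(image)
  if (max(image) <= 0) stop("floor undefined for an all-zero image")
  image[image == 0] <- mean(image) / 100
  image
}
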