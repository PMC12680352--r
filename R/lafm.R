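## Localization AFM: bicubic expansion, strict local-maximum peak detection,
## Gaussian peak rendering normalized to the stack maximum, and composition of
## the probability-weighted mean-height image.

#' LAFM reconstruction parameters
#'
#' @param expansionFactor integer >= 1; each frame is expanded by bicubic
#'   interpolation to \code{factor} times its linear size.  The default 3
#'   turns a 4 A/px scan into roughly 1.3 A/px.
#' @param kernelSigma width (sd, expanded pixels) of the Gaussian used to
#'   broaden detected peaks; default \code{expansionFactor / 2}.
#' @param minPeakHeight detection floor (Angstrom); only strict local maxima
#'   above this height count as peaks.
#' @return A parameter list for [composeLAFM()].
#' @export
lafmParams <- function(expansionFactor = 3, kernelSigma = expansionFactor / 2,
                       minPeakHeight = 0) {
  stopifnot(expansionFactor >= 1, kernelSigma > 0, minPeakHeight >= 0)
  list(expansionFactor = as.integer(expansionFactor),
       kernelSigma = kernelSigma, minPeakHeight = minPeakHeight)
}

#' Expand an image by bicubic interpolation
#'
#' Output dimensions are the input dimensions times \code{factor}.  A
#' Catmull-Rom bicubic kernel is used, which reproduces constant and linear
#' images exactly (away from the replicated border); negative interpolation
#' overshoot is clipped at 0 to preserve the non-negative height contract.
#'
#' @param image H x W numeric matrix.
#' @param factor integer >= 1; \code{factor = 1} returns the image unchanged.
#' @return (H * factor) x (W * factor) matrix.
#' @export
expandImage <- function(image, factor) {
  if (factor < 1) stop("expansion factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  pmax(resampleImage(image, nrow(image) * factor, ncol(image) * factor), 0)
}

#' Detect strict local maxima in an expanded frame
#'
#' A pixel is a peak iff it is strictly greater than all 8 neighbours and
#' exceeds \code{minPeakHeight}; border pixels are excluded and flat plateaus
#' never qualify (bicubic-interpolated data is generically plateau-free).
#'
#' @param image H x W numeric matrix (heights >= 0).
#' @param minPeakHeight detection floor (Angstrom).
#' @return data.frame with columns \code{row}, \code{col}, \code{height}, one
#'   row per peak (0 rows when none).
#' @export
detectPeaks <- function(image, minPeakHeight = 0) {
  H <- nrow(image); W <- ncol(image)
  if (H < 3 || W < 3)
    return(data.frame(row = integer(0), col = integer(0), height = numeric(0)))
  C <- image[2:(H - 1), 2:(W - 1), drop = FALSE]
  isMax <- C > minPeakHeight
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- image[2:(H - 1) + dr, 2:(W - 1) + dc, drop = FALSE]
    isMax <- isMax & (C > nb)
  }
  idx <- which(isMax, arr.ind = TRUE)
  data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
             height = C[isMax])
}

#' Render detected peaks of one frame as bounded Gaussians
#'
#' Each peak contributes a Gaussian of width \code{kernelSigma} centred at its
#' pixel, with amplitude equal to its real-space height divided by the stack
#' maximum (so amplitudes lie in [0, 1] and a peak at the stack maximum
#' renders to exactly 1 at its centre).  Overlapping contributions combine by
#' per-pixel maximum, keeping the frame map within [0, 1] as a detection
#' probability surrogate.
#'
#' @param peaks data.frame from [detectPeaks()].
#' @param stackMaxHeight global maximum height over the (expanded) stack,
#'   Angstrom, > 0.
#' @param shape output dimensions c(H, W).
#' @param kernelSigma Gaussian sd in pixels.
#' @return H x W matrix in [0, 1]; all zero when there are no peaks.
#' @export
renderPeaks <- function(peaks, stackMaxHeight, shape, kernelSigma) {
  if (stackMaxHeight <= 0) stop("degenerate stack: maximum height must be > 0")
  out <- matrix(0, shape[1], shape[2])
  if (!nrow(peaks)) return(out)
  rr <- seq_len(shape[1]); cc <- seq_len(shape[2])
  for (p in seq_len(nrow(peaks))) {
    amp <- peaks$height[p] / stackMaxHeight
    g <- amp * exp(-(outer((rr - peaks$row[p])^2, (cc - peaks$col[p])^2, `+`)) /
                     (2 * kernelSigma^2))
    out <- pmax(out, g)
  }
  out
}

#' Compose a LAFM image from a registered stack
#'
#' Every frame is expanded by bicubic interpolation, peaks are detected on the
#' expanded frames and rendered as height-normalized Gaussians; the rendered
#' maps are averaged pixel-wise over the stack into a cumulative peaking
#' probability image, which is multiplied by the per-pixel mean of the
#' expanded real-space heights to give the final LAFM image.  Deterministic,
#' and invariant under frame-order permutation.
#'
#' An all-zero stack has no height reference; it yields an all-zero LAFM image
#' with a warning.
#'
#' @param stack an [AFMStack-class] (assumed registered/aligned).
#' @param params a [lafmParams()] list.
#' @return A [LAFMImage-class].
#' @examples
#' st <- AFMStack(matrix(c(rep(0, 12), 5, rep(0, 12)), 5, 5), pixelSize = 4)
#' composeLAFM(st, lafmParams(expansionFactor = 2, kernelSigma = 1))
#' @export
composeLAFM <- function(stack, params = lafmParams()) {
  stopifnot(is(stack, "AFMStack"))
  n <- nFrames(stack)
  if (n < 1) stop("empty stack")
  f <- params$expansionFactor
  expanded <- lapply(seq_len(n), function(i) expandImage(frameAt(stack, i), f))
  shape <- dim(expanded[[1]])
  stackMax <- max(vapply(expanded, max, numeric(1)))
  ## per-pixel sorted accumulation: makes the means bit-identical under any
  ## frame permutation (plain running sums differ in the last ulp)
  meanSorted <- function(mats) {
    M <- vapply(mats, as.vector, numeric(prod(shape)))
    matrix(apply(M, 1, function(r) sum(sort(r))), shape[1], shape[2]) / n
  }
  meanHeight <- meanSorted(expanded)
  if (stackMax <= 0) {
    warning("all-zero stack: returning an all-zero LAFM image")
    prob <- matrix(0, shape[1], shape[2])
  } else {
    rendered <- lapply(seq_len(n), function(i) {
      pk <- detectPeaks(expanded[[i]], params$minPeakHeight)
      renderPeaks(pk, stackMax, shape, params$kernelSigma)
    })
    prob <- meanSorted(rendered)
  }
  new("LAFMImage", values = prob * meanHeight, probabilityMap = prob,
      meanHeightMap = meanHeight, pixelSize = stack@pixelSize / f,
      params = params)
}
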