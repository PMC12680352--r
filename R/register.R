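## Rigid-body (rotation + translation) intensity-based registration with a
## coarse rotation search, FFT cross-correlation translation initializer and
## Nelder-Mead refinement on the sum of squared differences.  The transform
## parameterization structurally forbids scale and shear.

#' Rigid transform constructor
#'
#' Rotation (degrees, about the geometric image centre) followed by
#' translation in pixels.  Composable and invertible; no scale or shear.
#'
#' @param rotationDeg rotation angle in degrees.
#' @param dx,dy translation in pixels (columns, rows).
#' @return A \code{RigidTransform} list.
#' @export
rigidTransform <- function(rotationDeg = 0, dx = 0, dy = 0) {
  structure(list(rotationDeg = rotationDeg, dx = dx, dy = dy),
            class = "RigidTransform")
}

#' Invert a rigid transform
#' @param t a [rigidTransform()].
#' @return The inverse \code{RigidTransform}.
#' @export
invertRigid <- function(t) {
  a <- -t$rotationDeg * pi / 180
  ## inverse: rotate by -theta, translate by -R(-theta) t
  dx <- -(t$dx * cos(a) - t$dy * sin(a))
  dy <- -(t$dx * sin(a) + t$dy * cos(a))
  rigidTransform(-t$rotationDeg, dx, dy)
}

#' Apply a rigid transform to an image
#'
#' Resamples the image under rotation about its centre plus translation,
#' with bilinear interpolation; pixels mapping outside the source are filled
#' with 0 (the membrane background), preserving the non-negative height
#' contract.  The identity transform returns the image unchanged, and pure
#' integer-pixel translations are exact shifts.
#'
#' @param image H x W numeric matrix.
#' @param t a [rigidTransform()].
#' @return Transformed H x W matrix.
#' @export
applyRigid <- function(image, t) {
  H <- nrow(image); W <- ncol(image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  a <- t$rotationDeg * pi / 180
  rows <- rep(seq_len(H), times = W)
  cols <- rep(seq_len(W), each = H)
  ## inverse mapping: source = R^-1 (dest - c - t) + c
  ry <- rows - cy - t$dy
  rx <- cols - cx - t$dx
  sx <- cos(a) * rx + sin(a) * ry + cx
  sy <- -sin(a) * rx + cos(a) * ry + cy
  matrix(bilinearSample(image, sy, sx, fill = 0), H, W)
}

## integer-pixel translation estimate by FFT cross-correlation
xcorrShift <- function(moving, reference) {
  F1 <- stats::fft(reference)
  F2 <- stats::fft(moving)
  cc <- Re(stats::fft(F1 * Conj(F2), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  H <- nrow(moving); W <- ncol(moving)
  dy <- unname(pk[1]) - 1; dx <- unname(pk[2]) - 1
  if (dy > H / 2) dy <- dy - H
  if (dx > W / 2) dx <- dx - W
  c(dx = dx, dy = dy)
}

ssdScore <- function(moving, reference, par) {
  tr <- applyRigid(moving, rigidTransform(par[1], par[2], par[3]))
  sum((tr - reference)^2)
}

#' Estimate the rigid transform aligning an image onto a reference
#'
#' Intensity-based least-squares rigid alignment: a coarse search over
#' candidate rotations (each with an FFT cross-correlation translation
#' estimate) picks the best starting point, which Nelder-Mead then refines on
#' the sum of squared differences with bilinear resampling.  Returns the
#' transform that maps \code{moving} onto \code{reference}.
#'
#' @param moving,reference H x W numeric matrices with nonzero content.
#' @param rotRange half-width of the rotation search interval (degrees).
#' @param rotStep coarse rotation step (degrees).
#' @return A [rigidTransform()].
#' @export
estimateRigid <- function(moving, reference, rotRange = 60, rotStep = 5,
                          init = NULL) {
  if (!identical(dim(moving), dim(reference)))
    stop("images must have identical dimensions")
  if (max(moving) <= 0 || max(reference) <= 0)
    stop("degenerate registration: blank image")
  best <- NULL; bestScore <- Inf
  angles <- if (is.null(init)) seq(-rotRange, rotRange, by = rotStep)
            else init$rotationDeg
  for (th in angles) {
    rotated <- applyRigid(moving, rigidTransform(th, 0, 0))
    sh <- xcorrShift(rotated, reference)
    par <- c(th, sh["dx"], sh["dy"])
    sc <- ssdScore(moving, reference, par)
    if (sc < bestScore) {
      bestScore <- sc
      best <- par
    }
  }
  if (!is.null(init)) {
    par <- c(init$rotationDeg, init$dx, init$dy)
    sc <- ssdScore(moving, reference, par)
    if (sc < bestScore) {
      bestScore <- sc
      best <- par
    }
  }
  opt <- stats::optim(best, function(p) ssdScore(moving, reference, p),
                      method = "Nelder-Mead",
                      control = list(maxit = 150, reltol = 1e-9))
  ## polish: restart once from the optimum (Nelder-Mead can stall early)
  opt <- stats::optim(opt$par, function(p) ssdScore(moving, reference, p),
                      method = "Nelder-Mead",
                      control = list(maxit = 80, reltol = 1e-10))
  out <- rigidTransform(opt$par[1], opt$par[2], opt$par[3])
  attr(out, "ssd") <- opt$value
  out
}

#' Register every frame of a stack to a reference
#'
#' @param stack an [AFMStack-class].
#' @param reference a frame index into the stack, or an H x W matrix.
#' @param sequentialInit seed each frame's search with the previous frame's
#'   transform (default TRUE).  Trajectory drift is slow and temporally
#'   correlated, so the previous transform is usually within the
#'   convergence basin and the coarse rotation sweep collapses to a single
#'   candidate; the full sweep still runs whenever the warm start is poor
#'   (its refined score is kept only if it beats the sweep's).
#' @param ... passed to [estimateRigid()].
#' @return A \code{RegisteredStack}: list with \code{stack} (transformed
#'   frames as an [AFMStack-class]), \code{transforms} (data.frame
#'   rotationDeg/dx/dy per frame) and \code{referenceIndex} (NA when an
#'   image was supplied).
#' @export
registerStack <- function(stack, reference, sequentialInit = TRUE, ...) {
  stopifnot(is(stack, "AFMStack"))
  refIdx <- NA_integer_
  if (length(reference) == 1 && is.numeric(reference)) {
    refIdx <- as.integer(reference)
    if (refIdx < 1 || refIdx > nFrames(stack)) stop("reference index out of range")
    refImg <- frameAt(stack, refIdx)
  } else {
    refImg <- as.matrix(reference)
  }
  n <- nFrames(stack)
  out <- array(0, dim(stack@heights))
  tf <- data.frame(rotationDeg = numeric(n), dx = numeric(n), dy = numeric(n))
  prev <- NULL
  ssds <- numeric(0)
  for (i in seq_len(n)) {
    if (!is.na(refIdx) && i == refIdx) {
      t <- rigidTransform(0, 0, 0)
      prev <- NULL
    } else {
      t <- estimateRigid(frameAt(stack, i), refImg, init = prev, ...)
      if (!is.null(prev) && length(ssds) >= 5 &&
          attr(t, "ssd") > 3 * stats::median(ssds)) {
        ## warm start missed the basin: redo with the full rotation sweep
        tFull <- estimateRigid(frameAt(stack, i), refImg, ...)
        if (attr(tFull, "ssd") < attr(t, "ssd")) t <- tFull
      }
      ssds <- c(ssds, attr(t, "ssd"))
      prev <- if (sequentialInit) t else NULL
    }
    out[, , i] <- pmax(applyRigid(frameAt(stack, i), t), 0)
    tf[i, ] <- c(t$rotationDeg, t$dx, t$dy)
  }
  list(stack = AFMStack(out, pixelSize = stack@pixelSize, code = stack@code,
                        meta = stack@meta),
       transforms = tf, referenceIndex = refIdx)
}
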