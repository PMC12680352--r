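## Structural similarity: local-statistics SSIM map, masked mean score,
## weighted reconstruction loss (with an analytic gradient used by the CAE
## trainer), LAFM quality profiles, and cluster-consistency metrics.

#' SSIM configuration
#'
#' Standard literature defaults: 11 x 11 Gaussian window with sd 1.5 px and
#' stabilization constants K1 = 0.01, K2 = 0.03.  Because LAFM height images
#' have no fixed dynamic range, \code{dataRange = NULL} uses the maximum value
#' over the compared pair.
#'
#' @param window odd window size in pixels, >= 3.
#' @param windowSigma Gaussian window sd in pixels.
#' @param K1,K2 stabilization constants, > 0.
#' @param dataRange dynamic range L, or NULL for the pairwise maximum.
#' @return An SSIM configuration list.
#' @export
ssimConfig <- function(window = 11, windowSigma = 1.5, K1 = 0.01, K2 = 0.03,
                       dataRange = NULL) {
  stopifnot(window %% 2 == 1, window >= 3, K1 > 0, K2 > 0)
  list(window = as.integer(window), windowSigma = windowSigma,
       K1 = K1, K2 = K2, dataRange = dataRange)
}

ssimRange <- function(x, y, cfg) {
  L <- cfg$dataRange
  if (is.null(L)) L <- max(max(x), max(y))
  if (L <= 0) L <- 1   # degenerate pair of all-zero images
  L
}

ssimStats <- function(x, y, cfg) {
  win <- gaussWindow(cfg$window, cfg$windowSigma)
  mx <- filterWindow(x, win)
  my <- filterWindow(y, win)
  sxx <- filterWindow(x * x, win) - mx^2
  syy <- filterWindow(y * y, win) - my^2
  sxy <- filterWindow(x * y, win) - mx * my
  L <- ssimRange(x, y, cfg)
  list(mx = mx, my = my, sxx = sxx, syy = syy, sxy = sxy,
       C1 = (cfg$K1 * L)^2, C2 = (cfg$K2 * L)^2, win = win)
}

#' Per-pixel SSIM map
#'
#' Local Gaussian-weighted means, variances and covariance feed the two-term
#' SSIM formula
#' \deqn{S = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'            {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}}
#' with \eqn{C_1 = (K_1 L)^2}, \eqn{C_2 = (K_2 L)^2}.  Values lie in [-1, 1];
#' \code{ssimMap(x, x)} is identically 1.
#'
#' @param x,y numeric matrices of identical dimensions.
#' @param cfg an [ssimConfig()].
#' @return Matrix of local SSIM values, same shape as the inputs.
#' @export
ssimMap <- function(x, y, cfg = ssimConfig()) {
  if (!identical(dim(x), dim(y))) stop("images must have identical dimensions")
  s <- ssimStats(x, y, cfg)
  A1 <- 2 * s$mx * s$my + s$C1
  A2 <- 2 * s$sxy + s$C2
  B1 <- s$mx^2 + s$my^2 + s$C1
  B2 <- s$sxx + s$syy + s$C2
  (A1 * A2) / (B1 * B2)
}

#' Foreground mask for a compared image pair
#'
#' Pixels where either image exceeds \code{thresholdFraction} of the pair
#' maximum.  The union condition keeps pixels where only one image has
#' protein, so one-sided differences remain visible.
#'
#' @param x,y numeric matrices of identical dimensions.
#' @param thresholdFraction fraction of the pair maximum, in (0, 1);
#'   default 0.05 (5 percent).
#' @return Logical matrix.
#' @export
pairMask <- function(x, y, thresholdFraction = 0.05) {
  stopifnot(thresholdFraction > 0, thresholdFraction < 1)
  thr <- thresholdFraction * max(max(x), max(y))
  x > thr | y > thr
}

#' Masked SSIM score
#'
#' SSIM is computed over the whole image; the mean is then taken only over
#' the foreground mask (pixels above \code{thresholdFraction} of the pair
#' maximum in either image), excluding the flat 0-height background that
#' would otherwise bias the score towards 1.  Symmetric in its arguments and
#' exactly 1 for identical images.
#'
#' @inheritParams ssimMap
#' @param thresholdFraction see [pairMask()].
#' @return A single score in [-1, 1].
#' @export
maskedSSIM <- function(x, y, cfg = ssimConfig(), thresholdFraction = 0.05) {
  m <- pairMask(x, y, thresholdFraction)
  if (!any(m))
    stop("degenerate comparison: no pixel above the mask threshold")
  mean(ssimMap(x, y, cfg)[m])
}

#' Weighted SSIM reconstruction loss
#'
#' Combines global SSIM (background fidelity) and masked SSIM (protein
#' features) into the reconstruction loss
#' \deqn{\mathrm{loss} = 1 - \frac{\alpha\,\mathrm{SSIM} +
#'   \beta\,\mathrm{SSIM}_{masked}}{\alpha + \beta}.}
#' Normalizing by \eqn{\alpha + \beta} makes equal weights invariant to their
#' common scale.  The loss is 0 iff the reconstruction is SSIM-perfect both
#' globally and on the mask, and never exceeds 2.
#'
#' @param x reference image; \code{xRec} its reconstruction.
#' @param xRec reconstructed image.
#' @param alpha,beta non-negative weights of global and masked SSIM; at least
#'   one must be positive.  Defaults are equal.
#' @param cfg an [ssimConfig()].
#' @param thresholdFraction mask threshold fraction.
#' @return Loss value in [0, 2].
#' @export
weightedSSIMLoss <- function(x, xRec, alpha = 0.5, beta = 0.5,
                             cfg = ssimConfig(), thresholdFraction = 0.05) {
  stopifnot(alpha >= 0, beta >= 0)
  if (alpha + beta <= 0) stop("at least one of alpha, beta must be positive")
  sGlobal <- if (alpha > 0) mean(ssimMap(x, xRec, cfg)) else 0
  sMasked <- if (beta > 0) maskedSSIM(x, xRec, cfg, thresholdFraction) else 0
  1 - (alpha * sGlobal + beta * sMasked) / (alpha + beta)
}

## Analytic gradient of mean-over-weights SSIM with respect to y, where
## weights is a per-pixel averaging weight image (uniform 1/N for global SSIM,
## mask/|mask| for masked SSIM).  Derived from the chain rule through the
## Gaussian-window local statistics; verified against finite differences in
## the test suite.  The data range L is held fixed (treated as a constant of
## the comparison, as during CAE training where images live in [0, 1]).
ssimGradY <- function(x, y, cfg, weights) {
  s <- ssimStats(x, y, cfg)
  A1 <- 2 * s$mx * s$my + s$C1
  A2 <- 2 * s$sxy + s$C2
  B1 <- s$mx^2 + s$my^2 + s$C1
  B2 <- s$sxx + s$syy + s$C2
  dS_dmy  <- (2 * s$mx * A2) / (B1 * B2) - (2 * s$my * A1 * A2) / (B1^2 * B2)
  dS_dsyy <- -(A1 * A2) / (B1 * B2^2)
  dS_dsxy <- (2 * A1) / (B1 * B2)
  w <- weights
  t1 <- filterWindow(w * dS_dmy, s$win)
  t2 <- filterWindow(w * dS_dsyy, s$win)
  t3 <- filterWindow(w * dS_dsyy * s$my, s$win)
  t4 <- filterWindow(w * dS_dsxy, s$win)
  t5 <- filterWindow(w * dS_dsxy * s$mx, s$win)
  t1 + 2 * (y * t2 - t3) + (x * t4 - t5)
}

## Gradient of weightedSSIMLoss with respect to xRec (fixed data range cfg).
weightedSSIMLossGrad <- function(x, xRec, alpha = 0.5, beta = 0.5,
                                 cfg = ssimConfig(), thresholdFraction = 0.05) {
  n <- length(x)
  g <- 0
  if (alpha > 0)
    g <- g + alpha * ssimGradY(x, xRec, cfg, matrix(1 / n, nrow(x), ncol(x)))
  if (beta > 0) {
    m <- pairMask(x, xRec, thresholdFraction)
    if (any(m))
      g <- g + beta * ssimGradY(x, xRec, cfg, m / sum(m))
  }
  -g / (alpha + beta)
}

#' LAFM quality profile over tip radius and pixel size
#'
#' Each stack is reconstructed with [composeLAFM()], resampled (bicubic) onto
#' the benchmark LAFM grid, and scored against the benchmark with
#' [maskedSSIM()].  Scores are banded at 0.9 / 0.7 / 0.5 into "very good",
#' "good", "acceptable" and "poor" quality classes.
#'
#' @param stacks list of [AFMStack-class] objects.
#' @param tipRadii,pixelSizes numeric vectors parallel to \code{stacks},
#'   giving the (R, P) cell of each stack.
#' @param benchmark a [LAFMImage-class] on the finest grid.
#' @param params [lafmParams()] used for each stack's reconstruction.
#' @param cfg an [ssimConfig()].
#' @return data.frame with columns tipRadius, pixelSize, score, quality.
#' @export
qualityProfile <- function(stacks, tipRadii, pixelSizes, benchmark,
                           params = lafmParams(), cfg = ssimConfig()) {
  stopifnot(length(stacks) == length(tipRadii),
            length(stacks) == length(pixelSizes))
  ref <- lafmValues(benchmark)
  score <- vapply(stacks, function(st) {
    img <- lafmValues(composeLAFM(st, params))
    res <- pmax(resampleImage(img, nrow(ref), ncol(ref)), 0)
    maskedSSIM(res, ref, cfg)
  }, numeric(1))
  quality <- cut(score, breaks = c(-Inf, 0.5, 0.7, 0.9, Inf),
                 labels = c("poor", "acceptable", "good", "very good"))
  data.frame(tipRadius = tipRadii, pixelSize = pixelSizes, score = score,
             quality = quality)
}

#' Per-cluster Jaccard consistency between two labelings
#'
#' Clusters of \code{labelsA} are matched greedily to clusters of
#' \code{labelsB} by maximal overlap; each matched pair is scored with the
#' Jaccard index |intersection| / |union| of their frame sets.  Identical
#' labelings (up to label permutation) score 1 on every cluster.
#'
#' @param labelsA,labelsB label vectors over the same frame index set.
#' @return data.frame with columns clusterA, clusterB, jaccard, sizeA, sizeB,
#'   ordered by decreasing cluster size in \code{labelsA}.
#' @export
jaccardConsistency <- function(labelsA, labelsB) {
  if (!length(labelsA) || length(labelsA) != length(labelsB))
    stop("labelings must be nonempty and cover the same frames")
  ta <- sort(table(labelsA), decreasing = TRUE)
  ub <- unique(labelsB)
  usedB <- character(0)
  out <- data.frame(clusterA = character(0), clusterB = character(0),
                    jaccard = numeric(0), sizeA = integer(0),
                    sizeB = integer(0), stringsAsFactors = FALSE)
  for (ca in names(ta)) {
    ia <- which(as.character(labelsA) == ca)
    cand <- setdiff(as.character(ub), usedB)
    if (!length(cand)) break
    ov <- vapply(cand, function(cb)
      sum(as.character(labelsB)[ia] == cb), numeric(1))
    cb <- cand[which.max(ov)]
    ib <- which(as.character(labelsB) == cb)
    ji <- length(intersect(ia, ib)) / length(union(ia, ib))
    usedB <- c(usedB, cb)
    out <- rbind(out, data.frame(clusterA = ca, clusterB = cb, jaccard = ji,
                                 sizeA = length(ia), sizeB = length(ib),
                                 stringsAsFactors = FALSE))
  }
  out
}
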