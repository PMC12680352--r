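## A small convolutional autoencoder for AFM topograph stacks, implemented as
## vectorized base-R linear algebra with analytic backpropagation through the
## weighted-SSIM reconstruction loss and Adam updates.  The whole pipeline is
## deterministic given the config seed.
##
## Architecture: stride-2 3x3 conv blocks with ReLU (channels per
## `convChannels`), a linear dense latent bottleneck, and a mirrored decoder
## (dense + ReLU, then nearest-neighbour x2 upsampling followed by 3x3 convs,
## sigmoid output).  Images are min-max normalized by the global stack
## maximum before training.

#' Configuration of the convolutional autoencoder
#'
#' @param latentDim latent feature vector length, >= 2 (default 64).
#' @param convChannels channel counts of the stride-2 encoder conv blocks
#'   (mirrored in the decoder); default c(16, 32, 64).  Input height/width
#'   must be divisible by \code{2^length(convChannels)}.
#' @param epochs training epochs, >= 1.
#' @param batchSize minibatch size.
#' @param learningRate Adam step size.
#' @param seed integer seed controlling weight init and batch order.
#' @param lossAlpha,lossBeta weights of global and masked SSIM in the
#'   reconstruction loss (defaults equal; see [weightedSSIMLoss()]).
#' @param ssimWindow SSIM window size used in the loss (odd; shrunk
#'   automatically for very small inputs).
#' @return A CAE configuration list.
#' @export
caeConfig <- function(latentDim = 64, convChannels = c(16, 32, 64),
                      epochs = 30, batchSize = 32, learningRate = 1e-3,
                      seed = 1, lossAlpha = 0.5, lossBeta = 0.5,
                      ssimWindow = 11) {
  stopifnot(latentDim >= 2, epochs >= 1, batchSize >= 1,
            length(convChannels) >= 1, all(convChannels >= 1))
  list(latentDim = as.integer(latentDim),
       convChannels = as.integer(convChannels),
       epochs = as.integer(epochs), batchSize = as.integer(batchSize),
       learningRate = learningRate, seed = as.integer(seed),
       lossAlpha = lossAlpha, lossBeta = lossBeta,
       ssimWindow = as.integer(ssimWindow))
}

## ---- layer plans -----------------------------------------------------------

## im2col plan for a 3x3 conv with pad 1 and given stride
convPlan <- function(Hin, Win, Cin, Cout, stride) {
  Hp <- Hin + 2L; Wp <- Win + 2L
  Hout <- (Hin - 1L) %/% stride + 1L
  Wout <- (Win - 1L) %/% stride + 1L
  Nout <- Hout * Wout
  K <- 9L * Cin
  ## padAssign: positions of the unpadded activation inside the padded vector
  rr <- rep(seq_len(Hin), times = Win * Cin)
  cc <- rep(rep(seq_len(Win), each = Hin), times = Cin)
  ch <- rep(seq_len(Cin), each = Hin * Win)
  padAssign <- (ch - 1L) * Hp * Wp + cc * Hp + rr + 1L
  ## idxFlat: for output pixel i (row-major within column-major image order)
  ## and tap k = (kr, kc, c), the padded-vector row index
  ho <- rep(seq_len(Hout), times = Wout)
  wo <- rep(seq_len(Wout), each = Hout)
  idx <- integer(Nout * K)
  k <- 0L
  for (c in seq_len(Cin)) for (kc in 1:3) for (kr in 1:3) {
    pr <- (ho - 1L) * stride + kr
    pc <- (wo - 1L) * stride + kc
    idx[k * Nout + seq_len(Nout)] <- (c - 1L) * Hp * Wp + (pc - 1L) * Hp + pr
    k <- k + 1L
  }
  list(Hin = Hin, Win = Win, Cin = Cin, Cout = Cout, stride = stride,
       Hp = Hp, Wp = Wp, Hout = Hout, Wout = Wout, Nout = Nout, K = K,
       padAssign = padAssign, idxFlat = idx, padLen = Hp * Wp * Cin)
}

## nearest-neighbour x2 upsample plan
upPlan <- function(Hin, Win, C) {
  Hout <- 2L * Hin; Wout <- 2L * Win
  r <- rep(seq_len(Hout), times = Wout * C)
  c <- rep(rep(seq_len(Wout), each = Hout), times = C)
  ch <- rep(seq_len(C), each = Hout * Wout)
  src <- (ch - 1L) * Hin * Win + ((c + 1L) %/% 2L - 1L) * Hin + (r + 1L) %/% 2L
  list(idx = src, Hout = Hout, Wout = Wout, outLen = Hout * Wout * C,
       inLen = Hin * Win * C)
}

## ---- forward / backward primitives ----------------------------------------

## A: (Hin*Win*Cin) x B activation matrix.  Returns out (Nout*Cout) x B plus
## the gathered columns needed for the weight gradient.
convForward <- function(A, W, b, plan) {
  B <- ncol(A)
  Ap <- matrix(0, plan$padLen, B)
  Ap[plan$padAssign, ] <- A
  Xall <- Ap[plan$idxFlat, , drop = FALSE]     # (Nout*K) x B
  out <- matrix(0, plan$Nout * plan$Cout, B)
  for (i in seq_len(B)) {
    Y <- matrix(Xall[, i], plan$Nout, plan$K) %*% W
    out[, i] <- as.vector(Y + rep(b, each = plan$Nout))
  }
  list(out = out, Xall = Xall)
}

convBackward <- function(dOut, cache, W, plan) {
  B <- ncol(dOut)
  dW <- matrix(0, plan$K, plan$Cout)
  db <- numeric(plan$Cout)
  dXall <- matrix(0, plan$Nout * plan$K, B)
  for (i in seq_len(B)) {
    dY <- matrix(dOut[, i], plan$Nout, plan$Cout)
    Xc <- matrix(cache$Xall[, i], plan$Nout, plan$K)
    dW <- dW + crossprod(Xc, dY)
    db <- db + colSums(dY)
    dXall[, i] <- as.vector(dY %*% t(W))
  }
  rs <- rowsum(dXall, plan$idxFlat)
  dAp <- matrix(0, plan$padLen, B)
  dAp[as.integer(rownames(rs)), ] <- rs
  list(dA = dAp[plan$padAssign, , drop = FALSE], dW = dW, db = db)
}

relu <- function(x) pmax(x, 0)

## ---- model construction ----------------------------------------------------

buildCAE <- function(H, W, cfg) {
  L <- length(cfg$convChannels)
  if (H %% 2^L != 0 || W %% 2^L != 0)
    stop("image dimensions must be divisible by 2^", L,
         " for ", L, " stride-2 conv blocks")
  chans <- c(1L, cfg$convChannels)
  encPlans <- vector("list", L)
  h <- H; w <- W
  for (l in seq_len(L)) {
    encPlans[[l]] <- convPlan(h, w, chans[l], chans[l + 1L], 2L)
    h <- encPlans[[l]]$Hout; w <- encPlans[[l]]$Wout
  }
  flat <- h * w * chans[L + 1L]
  decPlans <- vector("list", L)
  upPlans <- vector("list", L)
  dh <- h; dw <- w
  for (l in seq_len(L)) {
    cin <- chans[L + 2L - l]
    cout <- if (l == L) 1L else chans[L + 1L - l]
    upPlans[[l]] <- upPlan(dh, dw, cin)
    dh <- upPlans[[l]]$Hout; dw <- upPlans[[l]]$Wout
    decPlans[[l]] <- convPlan(dh, dw, cin, cout, 1L)
  }
  list(H = H, W = W, L = L, chans = chans, flat = flat,
       hBottom = h, wBottom = w, encPlans = encPlans,
       decPlans = decPlans, upPlans = upPlans)
}

initCAEParams <- function(arch, cfg) {
  heInit <- function(nr, nc, fanIn)
    matrix(rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)
  p <- list()
  for (l in seq_len(arch$L)) {
    pl <- arch$encPlans[[l]]
    p[[paste0("encW", l)]] <- heInit(pl$K, pl$Cout, pl$K)
    p[[paste0("encB", l)]] <- numeric(pl$Cout)
  }
  p$latW <- heInit(cfg$latentDim, arch$flat, arch$flat)
  p$latB <- numeric(cfg$latentDim)
  p$decW0 <- heInit(arch$flat, cfg$latentDim, cfg$latentDim)
  p$decB0 <- numeric(arch$flat)
  for (l in seq_len(arch$L)) {
    pl <- arch$decPlans[[l]]
    p[[paste0("decW", l)]] <- heInit(pl$K, pl$Cout, pl$K)
    p[[paste0("decB", l)]] <- numeric(pl$Cout)
  }
  p
}

## Full forward pass.  X: (H*W) x B of images in [0, 1].
caeForward <- function(X, p, arch, needCache = TRUE) {
  caches <- list()
  A <- X
  for (l in seq_len(arch$L)) {
    cf <- convForward(A, p[[paste0("encW", l)]], p[[paste0("encB", l)]],
                      arch$encPlans[[l]])
    Z <- cf$out
    A <- relu(Z)
    if (needCache) caches[[paste0("enc", l)]] <- list(X = cf$Xall, Z = Z)
  }
  lat <- p$latW %*% A + p$latB          # linear latent
  if (needCache) caches$preLat <- A
  Zd <- p$decW0 %*% lat + p$decB0
  Ad <- relu(Zd)
  if (needCache) caches$dec0 <- list(lat = lat, Z = Zd)
  A <- Ad
  for (l in seq_len(arch$L)) {
    up <- arch$upPlans[[l]]
    Au <- A[up$idx, , drop = FALSE]
    cf <- convForward(Au, p[[paste0("decW", l)]], p[[paste0("decB", l)]],
                      arch$decPlans[[l]])
    Z <- cf$out
    A <- if (l == arch$L) 1 / (1 + exp(-Z)) else relu(Z)
    if (needCache) caches[[paste0("dec", l)]] <- list(X = cf$Xall, Z = Z)
  }
  list(recon = A, latent = lat, caches = caches)
}

caeBackward <- function(dRecon, fwd, p, arch) {
  g <- list()
  A <- dRecon
  out <- fwd$recon
  for (l in rev(seq_len(arch$L))) {
    cache <- fwd$caches[[paste0("dec", l)]]
    dZ <- if (l == arch$L) A * out * (1 - out) else A * (cache$Z > 0)
    bk <- convBackward(dZ, list(Xall = cache$X), p[[paste0("decW", l)]],
                       arch$decPlans[[l]])
    g[[paste0("decW", l)]] <- bk$dW
    g[[paste0("decB", l)]] <- bk$db
    up <- arch$upPlans[[l]]
    rs <- rowsum(bk$dA, up$idx)
    dAin <- matrix(0, up$inLen, ncol(A))
    dAin[as.integer(rownames(rs)), ] <- rs
    A <- dAin
  }
  dZ0 <- A * (fwd$caches$dec0$Z > 0)
  g$decW0 <- dZ0 %*% t(fwd$caches$dec0$lat)
  g$decB0 <- rowSums(dZ0)
  dLat <- t(p$decW0) %*% dZ0
  g$latW <- dLat %*% t(fwd$caches$preLat)
  g$latB <- rowSums(dLat)
  A <- t(p$latW) %*% dLat
  for (l in rev(seq_len(arch$L))) {
    cache <- fwd$caches[[paste0("enc", l)]]
    dZ <- A * (cache$Z > 0)
    bk <- convBackward(dZ, list(Xall = cache$X), p[[paste0("encW", l)]],
                       arch$encPlans[[l]])
    g[[paste0("encW", l)]] <- bk$dW
    g[[paste0("encB", l)]] <- bk$db
    A <- bk$dA
  }
  g
}

## ---- training --------------------------------------------------------------

#' Train the convolutional autoencoder on a stack
#'
#' Frames are normalized to [0, 1] by the global stack maximum and the CAE is
#' trained end-to-end to minimize the weighted SSIM reconstruction loss
#' \code{1 - (alpha * SSIM + beta * SSIM_masked) / (alpha + beta)} (see
#' [weightedSSIMLoss()]) with Adam.  All randomness (weight init, batch
#' order) derives from \code{cfg$seed}, so two runs with the same config give
#' identical weights.
#'
#' @param stack an [AFMStack-class]; depth must be at least the batch size.
#' @param cfg a [caeConfig()].
#' @param verbose print per-epoch losses.
#' @return An object of class \code{"lafmCAE"}: list with \code{params},
#'   \code{arch}, \code{cfg}, \code{stackMax} (normalization constant) and
#'   \code{lossHistory} (mean epoch loss).
#' @seealso [extractLFV()], [dsc()]
#' @export
trainCAE <- function(stack, cfg = caeConfig(), verbose = FALSE) {
  stopifnot(is(stack, "AFMStack"))
  d <- dim(stack@heights)
  n <- d[3]
  if (n < cfg$batchSize)
    stop("stack depth (", n, ") must be at least the batch size (",
         cfg$batchSize, ")")
  stackMax <- max(stack@heights)
  if (stackMax <= 0) stackMax <- 1
  X <- matrix(stack@heights, d[1] * d[2], n) / stackMax
  arch <- buildCAE(d[1], d[2], cfg)
  win <- min(cfg$ssimWindow, 2L * ((min(d[1], d[2]) - 1L) %/% 2L) - 1L)
  lossCfg <- ssimConfig(window = max(win, 3L), dataRange = 1)
  withPrivateSeed(cfg$seed, {
    p <- initCAEParams(arch, cfg)
    m <- lapply(p, function(w) w * 0)
    v <- lapply(p, function(w) w * 0)
    t0 <- 0
    lossHistory <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      epLoss <- 0; nb <- 0
      for (start in seq(1, n, by = cfg$batchSize)) {
        ids <- ord[start:min(start + cfg$batchSize - 1, n)]
        Xb <- X[, ids, drop = FALSE]
        fwd <- caeForward(Xb, p, arch)
        dRecon <- matrix(0, nrow(Xb), ncol(Xb))
        bl <- 0
        for (i in seq_along(ids)) {
          xi <- matrix(Xb[, i], d[1], d[2])
          yi <- matrix(fwd$recon[, i], d[1], d[2])
          bl <- bl + weightedSSIMLoss(xi, yi, cfg$lossAlpha, cfg$lossBeta,
                                      lossCfg)
          dRecon[, i] <- as.vector(
            weightedSSIMLossGrad(xi, yi, cfg$lossAlpha, cfg$lossBeta,
                                 lossCfg)) / length(ids)
        }
        bl <- bl / length(ids)
        if (!is.finite(bl)) stop("training diverged: non-finite loss")
        g <- caeBackward(dRecon, fwd, p, arch)
        t0 <- t0 + 1
        for (nm in names(p)) {
          m[[nm]] <- 0.9 * m[[nm]] + 0.1 * g[[nm]]
          v[[nm]] <- 0.999 * v[[nm]] + 0.001 * g[[nm]]^2
          mh <- m[[nm]] / (1 - 0.9^t0)
          vh <- v[[nm]] / (1 - 0.999^t0)
          p[[nm]] <- p[[nm]] - cfg$learningRate * mh / (sqrt(vh) + 1e-8)
        }
        epLoss <- epLoss + bl; nb <- nb + 1
      }
      lossHistory[ep] <- epLoss / nb
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.5f", ep, cfg$epochs,
                        lossHistory[ep]))
    }
    structure(list(params = p, arch = arch, cfg = cfg, stackMax = stackMax,
                   lossHistory = lossHistory), class = "lafmCAE")
  })
}

#' @export
print.lafmCAE <- function(x, ...) {
  cat(sprintf(
    "lafmCAE: %dx%d input, latent %d, channels [%s]; final loss %.4f\n",
    x$arch$H, x$arch$W, x$cfg$latentDim,
    paste(x$cfg$convChannels, collapse = ", "),
    utils::tail(x$lossHistory, 1)))
  invisible(x)
}

#' Reconstruct frames with a trained CAE
#'
#' @param model a trained \code{"lafmCAE"} from [trainCAE()].
#' @param stack an [AFMStack-class] with the training resolution.
#' @return An H x W x N array of reconstructions on the normalized [0, 1]
#'   scale.
#' @export
reconstructFrames <- function(model, stack) {
  d <- dim(stack@heights)
  if (d[1] != model$arch$H || d[2] != model$arch$W)
    stop("stack resolution does not match the trained model")
  X <- matrix(stack@heights, d[1] * d[2], d[3]) / model$stackMax
  out <- caeForward(X, model$params, model$arch, needCache = FALSE)$recon
  array(out, d)
}

#' Extract latent feature vectors
#'
#' Applies the trained encoder to every frame (after the model's stored
#' normalization) and returns one latent feature vector per frame, in stack
#' order.  Deterministic; duplicate frames map to identical rows.
#'
#' @param model a trained \code{"lafmCAE"}.
#' @param stack an [AFMStack-class] with the training resolution.
#' @return N x latentDim numeric matrix.
#' @export
extractLFV <- function(model, stack) {
  d <- dim(stack@heights)
  if (d[1] != model$arch$H || d[2] != model$arch$W)
    stop("stack resolution does not match the trained model")
  X <- matrix(stack@heights, d[1] * d[2], d[3]) / model$stackMax
  arch <- model$arch; p <- model$params
  A <- X
  for (l in seq_len(arch$L)) {
    A <- relu(convForward(A, p[[paste0("encW", l)]], p[[paste0("encB", l)]],
                          arch$encPlans[[l]])$out)
  }
  t(p$latW %*% A + p$latB)
}
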