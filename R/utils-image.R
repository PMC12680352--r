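## Internal image utilities: separable bicubic resampling, Gaussian filtering
## via dense band matrices, bilinear rigid warps, and RNG hygiene.

## Keys/Catmull-Rom cubic kernel (a = -0.5); interpolates, reproduces
## polynomials up to degree 1 exactly.
cubicKernel <- function(s, a = -0.5) {
  s <- abs(s)
  w <- numeric(length(s))
  i1 <- s <= 1
  i2 <- s > 1 & s < 2
  w[i1] <- (a + 2) * s[i1]^3 - (a + 3) * s[i1]^2 + 1
  w[i2] <- a * s[i2]^3 - 5 * a * s[i2]^2 + 8 * a * s[i2] - 4 * a
  w
}

## nOut x nIn interpolation matrix mapping pixel-center samples of a 1D signal
## to a resampled grid; centers aligned as in standard image resizing:
## src = (dst + 0.5) * nIn/nOut - 0.5.  Border handled by index clamping
## (replicate padding).
resampleMatrix <- function(nIn, nOut, kernel = c("cubic", "linear")) {
  kernel <- match.arg(kernel)
  M <- matrix(0, nOut, nIn)
  scale <- nIn / nOut
  for (i in seq_len(nOut)) {
    src <- (i - 0.5) * scale - 0.5           # 0-based source coordinate
    base <- floor(src)
    if (kernel == "cubic") {
      taps <- base + (-1:2)
      w <- cubicKernel(src - taps)
    } else {
      taps <- base + 0:1
      w <- c(1 - (src - base), src - base)
    }
    taps <- pmin(pmax(taps, 0), nIn - 1) + 1  # clamp, to 1-based
    for (k in seq_along(taps)) M[i, taps[k]] <- M[i, taps[k]] + w[k]
  }
  M
}

## Resample an H x W image to newH x newW (bicubic by default).
resampleImage <- function(img, newH, newW, kernel = "cubic") {
  Ry <- resampleMatrix(nrow(img), newH, kernel)
  Rx <- resampleMatrix(ncol(img), newW, kernel)
  Ry %*% img %*% t(Rx)
}

## n x n Gaussian filtering matrix with reflective (symmetric) boundary.
## gaussFilterMatrix(n, sigma) %*% X filters columns of X along length-n axis.
gaussFilterMatrix <- function(n, sigma, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + seq(-radius, radius)
    ## reflect indices about the borders (symmetric padding, no repeat of edge)
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    idx <- pmin(pmax(idx, 1L), n)
    for (k2 in seq_along(idx)) M[i, idx[k2]] <- M[i, idx[k2]] + k[k2]
  }
  M
}

## Gaussian window weights for SSIM: (2r+1) x (2r+1), normalized to sum 1.
gaussWindow <- function(size, sigma) {
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

## 2D correlation of image with a separable (or full) window, symmetric
## boundary, same-size output.  win must be odd-sized square.  Band matrices
## are cached per (kernel, size) because SSIM-based training calls this in a
## tight loop.
.bandCache <- new.env(parent = emptyenv())

filterWindow <- function(img, win) {
  n <- nrow(win)
  r <- (n - 1L) %/% 2L
  wkey <- paste0("w", n, "_", paste(signif(win[, r + 1L], 10), collapse = ","))
  sep <- get0(wkey, envir = .bandCache)
  if (is.null(sep)) {
    ## separate via SVD rank-1 (Gaussian windows are exactly rank 1)
    sv <- svd(win, nu = 1, nv = 1)
    sgn <- sign(sum(sv$u[, 1]))
    sep <- list(ky = sgn * sv$u[, 1] * sqrt(sv$d[1]),
                kx = sgn * sv$v[, 1] * sqrt(sv$d[1]))
    assign(wkey, sep, envir = .bandCache)
  }
  H <- nrow(img); W <- ncol(img)
  keyY <- paste0(wkey, "_y", H)
  keyX <- paste0(wkey, "_x", W)
  My <- get0(keyY, envir = .bandCache)
  if (is.null(My)) {
    My <- bandFilterMatrix(H, sep$ky, r)
    assign(keyY, My, envir = .bandCache)
  }
  Mx <- get0(keyX, envir = .bandCache)
  if (is.null(Mx)) {
    Mx <- bandFilterMatrix(W, sep$kx, r)
    assign(keyX, Mx, envir = .bandCache)
  }
  My %*% img %*% t(Mx)
}

bandFilterMatrix <- function(n, k, r) {
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + seq(-r, r)
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
    idx <- pmin(pmax(idx, 1L), n)
    for (j in seq_along(idx)) M[i, idx[j]] <- M[i, idx[j]] + k[j]
  }
  M
}

## Evaluate image at fractional (row, col) positions by bilinear
## interpolation; positions outside the image give `fill`.
bilinearSample <- function(img, rows, cols, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  out <- numeric(length(rows))
  valid <- r0 >= 1 & r0 + 1 <= H & c0 >= 1 & c0 + 1 <= W &
    is.finite(rows) & is.finite(cols)
  ## exact border rows/cols (fr or fc == 0 at the last index) handled by
  ## clamping the +1 neighbor when its weight is zero
  r1 <- pmin(r0 + 1, H); c1 <- pmin(c0 + 1, W)
  edge <- r0 == H & fr == 0 | c0 == W & fc == 0
  valid2 <- (r0 >= 1 & r0 <= H & c0 >= 1 & c0 <= W) & (valid | edge)
  out[] <- fill
  v <- which(valid2)
  if (length(v)) {
    ii <- function(r, c) img[cbind(r, c)]
    out[v] <- (1 - fr[v]) * (1 - fc[v]) * ii(r0[v], c0[v]) +
      (1 - fr[v]) * fc[v] * ii(r0[v], c1[v]) +
      fr[v] * (1 - fc[v]) * ii(r1[v], c0[v]) +
      fr[v] * fc[v] * ii(r1[v], c1[v])
  }
  out
}

## Run code with a private, seeded RNG stream; restores the caller's
## .Random.seed afterwards so library calls do not perturb user scripts.
withPrivateSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
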