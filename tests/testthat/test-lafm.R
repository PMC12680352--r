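test_that("expansion is exact on constants and the identity at factor 1", {
  img <- matrix(3.5, 6, 6)
  expect_identical(expandImage(img, 1), img)
  expect_equal(max(abs(expandImage(img, 4) - 3.5)), 0)
  expect_error(expandImage(img, 0), "factor")
})

test_that("bicubic expansion reproduces a linear ramp in the interior", {
  f <- 3
  img <- outer(1:10, 1:10, function(i, j) 2 * i + 3 * j)
  ex <- expandImage(img, f)
  truth <- outer(1:30, 1:30, function(I, J)
    2 * ((I - 0.5) / f + 0.5) + 3 * ((J - 0.5) / f + 0.5))
  interior <- 6:24    # clear of the replicated border
  expect_lt(max(abs(ex[interior, interior] - truth[interior, interior])), 1e-6)
})

test_that("peak detection finds strict 8-neighbour maxima only", {
  m <- matrix(0, 9, 9)
  m[5, 5] <- 3; m[4, 5] <- 1
  pk <- detectPeaks(m)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$row, pk$col, pk$height), c(5, 5, 3))
  ## constant image: no strict maxima
  expect_equal(nrow(detectPeaks(matrix(2, 8, 8))), 0)
  ## two distant bumps vs an exhaustive neighbourhood-scan oracle
  m2 <- matrix(0, 15, 15)
  m2[4, 4] <- 5; m2[12, 11] <- 4
  m2[4, 5] <- m2[3, 4] <- 2; m2[12, 12] <- 1.5
  pk2 <- detectPeaks(m2)
  oracle <- list()
  for (i in 2:14) for (j in 2:14) {
    nb <- m2[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (m2[i, j] > 0 && sum(nb >= m2[i, j]) == 1) {
      oracle[[length(oracle) + 1]] <- c(i, j)
    }
  }
  expect_equal(nrow(pk2), length(oracle))
  expect_setequal(paste(pk2$row, pk2$col),
                  vapply(oracle, function(p) paste(p[1], p[2]), ""))
  ## border peaks are excluded, sub-threshold peaks filtered
  m3 <- matrix(0, 5, 5); m3[1, 3] <- 9; m3[3, 3] <- 0.4
  expect_equal(nrow(detectPeaks(m3, minPeakHeight = 0.5)), 0)
})

test_that("rendered peaks follow the Gaussian closed form and max-combine", {
  pk <- data.frame(row = 5, col = 5, height = 5)
  r <- renderPeaks(pk, stackMaxHeight = 10, shape = c(9, 9), kernelSigma = 1.5)
  expect_equal(r[5, 5], 0.5)
  expect_equal(r[5, 7], 0.5 * exp(-4 / (2 * 1.5^2)), tolerance = 1e-12)
  expect_equal(r[8, 9], 0.5 * exp(-25 / (2 * 1.5^2)), tolerance = 1e-12)
  ## a peak at the stack max renders to exactly 1 at its centre
  r1 <- renderPeaks(data.frame(row = 3, col = 3, height = 10), 10,
                    c(9, 9), 1)
  expect_equal(r1[3, 3], 1)
  expect_true(all(r1 >= 0 & r1 <= 1))
  ## overlapping peaks combine by maximum, bounded by 1
  pk2 <- data.frame(row = c(4, 5), col = c(4, 5), height = c(10, 10))
  r2 <- renderPeaks(pk2, 10, c(9, 9), 2)
  expect_true(all(r2 <= 1 + 1e-12))
  expect_equal(r2[4, 4], 1)
  ## no peaks -> all zero; degenerate stack max -> error
  expect_true(all(renderPeaks(pk[0, ], 10, c(5, 5), 1) == 0))
  expect_error(renderPeaks(pk, 0, c(5, 5), 1), "degenerate")
})

test_that("LAFM composition satisfies its probability contracts", {
  fr1 <- matrix(0, 9, 9); fr1[3, 3] <- 5
  fr2 <- matrix(0, 9, 9); fr2[7, 7] <- 5
  st <- AFMStack(list(fr1, fr2), pixelSize = 4)
  lf <- composeLAFM(st, lafmParams(expansionFactor = 1, kernelSigma = 0.4))
  p <- probabilityMap(lf)
  expect_true(all(p >= 0 & p <= 1))
  ## equal-height alternating peaks at the stack max: probability 0.5 each
  expect_equal(p[3, 3], 0.5)
  expect_equal(p[7, 7], 0.5)
  expect_equal(lafmValues(lf), p * meanHeightMap(lf))
  ## identical single-peak frames: probability 1 at the peak
  stSame <- AFMStack(list(fr1, fr1, fr1), pixelSize = 4)
  lfSame <- composeLAFM(stSame, lafmParams(1, 0.4))
  expect_equal(probabilityMap(lfSame)[3, 3], 1)
})

test_that("LAFM output is invariant under frame permutation", {
  fx <- memoFixture("lafmPermStack", function() {
    renderRecipe(pseudoProteinRecipe(2, nFrames = 12, seed = 4),
                 tip = TipModel(20), pixelSize = 4, extent = 32)
  })
  st <- fx$stack
  perm <- rev(seq_len(nFrames(st)))
  stPerm <- AFMStack(heights(st)[, , perm], pixelSize = pixelSize(st))
  p <- lafmParams(expansionFactor = 2)
  expect_identical(lafmValues(composeLAFM(st, p)),
                   lafmValues(composeLAFM(stPerm, p)))
})

test_that("all-zero stacks take the degenerate path", {
  st <- AFMStack(array(0, c(6, 6, 3)), pixelSize = 2)
  expect_warning(lf <- composeLAFM(st, lafmParams(2)), "all-zero")
  expect_true(all(lafmValues(lf) == 0))
})

test_that("LAFM localizes a sub-pixel fluctuating peak at its mean position", {
  ## single atom jittering by ~0.4 A around (1, 1) scanned at 4 A/px: the
  ## acquisition argmax is pinned to one pixel, but the expanded LAFM argmax
  ## must land within one expanded pixel of the true mean position
  withr::with_seed(13, {
    frames <- lapply(1:40, function(i)
      AtomSet(matrix(c(1 + rnorm(1, sd = 0.4), 1 + rnorm(1, sd = 0.4), 6),
                     1, 3), radii = 2))
  })
  st <- renderStack(frames, TipModel(10), ScanGrid(-16, 16, -16, 16, 4))
  f <- 4
  lf <- composeLAFM(st, lafmParams(expansionFactor = f, kernelSigma = 1))
  am <- which(lafmValues(lf) == max(lafmValues(lf)), arr.ind = TRUE)[1, ]
  ## true mean position (1, 1) in expanded pixel coordinates
  px <- 4 / f
  expCol <- (1 - (-16)) / px + 0.5
  expRow <- (1 - (-16)) / px + 0.5
  expect_lt(abs(am[1] - expRow), 1 + 1e-9)
  expect_lt(abs(am[2] - expCol), 1 + 1e-9)
})
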