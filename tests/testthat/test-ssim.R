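blobImage <- function(cr, cc, amp, shape = c(24, 24), sigma = 2) {
  outer(seq_len(shape[1]), seq_len(shape[2]), function(i, j)
    amp * exp(-((i - cr)^2 + (j - cc)^2) / (2 * sigma^2)))
}

test_that("SSIM map is 1 on identical images and bounded in [-1, 1]", {
  withr::with_seed(1, x <- matrix(runif(400, 0, 8), 20, 20))
  expect_equal(max(abs(ssimMap(x, x) - 1)), 0, tolerance = 1e-12)
  ## anti-correlated content can push local values negative but never
  ## outside [-1, 1]
  y <- max(x) - x
  sm <- ssimMap(x, y)
  expect_true(all(sm >= -1 - 1e-9 & sm <= 1 + 1e-9))
  expect_true(any(sm < 0))
  expect_error(ssimMap(x, matrix(0, 3, 3)), "dimensions")
})

test_that("constant-offset pair matches the closed-form luminance term", {
  x <- matrix(2, 16, 16)
  y <- x + 1
  cfg <- ssimConfig(dataRange = 5)
  C1 <- (0.01 * 5)^2; C2 <- (0.03 * 5)^2
  ## constant images: variances and covariance vanish, map is uniform
  expected <- (2 * 2 * 3 + C1) / (4 + 9 + C1)
  sm <- ssimMap(x, y, cfg)
  expect_equal(max(abs(sm - expected)), 0, tolerance = 1e-9)
})

test_that("masked SSIM uses the 5 percent pair-max union mask", {
  x <- blobImage(8, 8, 10)          # pair max 10 -> threshold 0.5
  y <- blobImage(17, 17, 8)
  cfg <- ssimConfig()
  mask <- x > 0.5 | y > 0.5
  expect_equal(pairMask(x, y), mask)
  ## direct oracle recomputation: mean of the full map over the mask
  expect_equal(maskedSSIM(x, y, cfg), mean(ssimMap(x, y, cfg)[mask]),
               tolerance = 1e-12)
  ## symmetry and self-similarity
  expect_equal(maskedSSIM(x, y, cfg), maskedSSIM(y, x, cfg))
  expect_equal(maskedSSIM(x, x, cfg), 1)
  ## empty mask -> degenerate-comparison error
  expect_error(maskedSSIM(matrix(0, 8, 8), matrix(0, 8, 8)), "degenerate")
})

test_that("weighted SSIM loss recomposes from its parts and hits 0 and its limits", {
  x <- blobImage(10, 12, 6)
  y <- blobImage(11, 12, 5.5)
  cfg <- ssimConfig(dataRange = 6)
  expect_equal(weightedSSIMLoss(x, x, cfg = cfg), 0, tolerance = 1e-12)
  ## alpha only: reduces to 1 - mean SSIM
  expect_equal(weightedSSIMLoss(x, y, alpha = 1, beta = 0, cfg = cfg),
               1 - mean(ssimMap(x, y, cfg)), tolerance = 1e-12)
  ## equal weights: 1 - average of the two scores computed independently
  expect_equal(weightedSSIMLoss(x, y, 0.5, 0.5, cfg),
               1 - (mean(ssimMap(x, y, cfg)) + maskedSSIM(x, y, cfg)) / 2,
               tolerance = 1e-12)
  ## weight normalization: common scale of (alpha, beta) is irrelevant
  expect_equal(weightedSSIMLoss(x, y, 1, 1, cfg),
               weightedSSIMLoss(x, y, 0.5, 0.5, cfg), tolerance = 1e-12)
  expect_error(weightedSSIMLoss(x, y, 0, 0), "positive")
  ## bounded by [0, 2]
  l <- weightedSSIMLoss(x, max(x) - x, cfg = cfg)
  expect_gte(l, 0); expect_lte(l, 2)
})

test_that("analytic loss gradient matches central finite differences", {
  withr::with_seed(3, {
    x <- matrix(runif(64), 8, 8)
    y <- matrix(runif(64), 8, 8)
  })
  cfg <- ssimConfig(window = 5, dataRange = 1)
  g <- LAFMkit:::weightedSSIMLossGrad(x, y, 0.5, 0.5, cfg)
  num <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    e <- 1e-6
    yp <- y; yp[i, j] <- y[i, j] + e
    ym <- y; ym[i, j] <- y[i, j] - e
    num[i, j] <- (weightedSSIMLoss(x, yp, 0.5, 0.5, cfg) -
                  weightedSSIMLoss(x, ym, 0.5, 0.5, cfg)) / (2 * e)
  }
  expect_lt(max(abs(g - num)) / max(abs(num)), 1e-6)
})

test_that("quality profile cells equal standalone metric calls and degrade with R", {
  ## fixture where larger tips provably blur: two nearby bumps
  atoms <- AtomSet(rbind(c(-4, 0, 6), c(4, 0, 6)), radii = 2)
  grid <- ScanGrid(-16, 16, -16, 16, 2)
  stacks <- lapply(c(2, 10, 20), function(R)
    renderStack(list(atoms), TipModel(R), grid))
  bench <- composeLAFM(stacks[[1]], lafmParams(2))
  qp <- qualityProfile(stacks, tipRadii = c(2, 10, 20),
                       pixelSizes = c(2, 2, 2), benchmark = bench,
                       params = lafmParams(2))
  expect_equal(qp$score[1], 1, tolerance = 1e-9)
  expect_true(all(diff(qp$score) <= 1e-12))  # non-increasing in R
  ## composition consistency: a cell equals the standalone call
  img3 <- lafmValues(composeLAFM(stacks[[3]], lafmParams(2)))
  res3 <- pmax(LAFMkit:::resampleImage(img3, nrow(lafmValues(bench)),
                                       ncol(lafmValues(bench))), 0)
  expect_equal(qp$score[3], maskedSSIM(res3, lafmValues(bench)),
               tolerance = 1e-12)
  expect_equal(as.character(qp$quality[1]), "very good")
})

test_that("Jaccard consistency counts overlaps after greedy matching", {
  a <- rep(c(1, 2), each = 100)
  expect_true(all(jaccardConsistency(a, a)$jaccard == 1))
  ## swapped ids: label-permutation invariance
  b <- rep(c(9, 4), each = 100)
  expect_true(all(jaccardConsistency(a, b)$jaccard == 1))
  ## one frame moved between two clusters of size 100: the donor pair keeps
  ## 99 of 100 frames, the acceptor pair 100 of 101
  b2 <- a; b2[100] <- 2
  ji <- jaccardConsistency(a, b2)
  expect_equal(sort(ji$jaccard), c(99 / 100, 100 / 101), tolerance = 1e-12)
  expect_error(jaccardConsistency(integer(0), integer(0)), "nonempty")
})
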