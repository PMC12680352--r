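test_that("CAE training is deterministic and its loss trends downward", {
  fx <- twoConformerStack()
  st <- AFMStack(heights(fx$stack)[, , 1:64], pixelSize = 2)
  cfg <- testCae(epochs = 4, seed = 9)
  m1 <- trainCAE(st, cfg)
  m2 <- trainCAE(st, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$lossHistory, m2$lossHistory)
  ## non-increasing trend: last epoch clearly below the first
  expect_lt(tail(m1$lossHistory, 1), m1$lossHistory[1])
  expect_true(all(is.finite(m1$lossHistory)))
})

test_that("a constant stack is learnable towards zero loss", {
  st <- AFMStack(array(rep(blob <- {
    b <- matrix(0, 32, 32); b[10:20, 10:20] <- 5; b
  }, 40), c(32, 32, 40)), pixelSize = 2)
  m <- trainCAE(st, testCae(epochs = 25, seed = 2))
  expect_lt(tail(m$lossHistory, 1), 0.2)
  expect_lt(tail(m$lossHistory, 1), m$lossHistory[1] / 4)
})

test_that("reconstruction quality reaches the frozen fixture bound", {
  ## bound frozen from a reference run of this configuration (mean SSIM 0.87)
  fx <- memoFixture("twoConf100", function() {
    renderRecipe(pseudoProteinRecipe(2, nFrames = 100, seed = 11),
                 tip = TipModel(20), pixelSize = 2, extent = 32)
  })
  m <- trainCAE(fx$stack, testCae(epochs = 30, seed = 5))
  rec <- reconstructFrames(m, fx$stack)
  X <- heights(fx$stack) / m$stackMax
  cfg <- ssimConfig(dataRange = 1)
  ss <- vapply(seq_len(nFrames(fx$stack)), function(i)
    mean(ssimMap(X[, , i], rec[, , i], cfg)), numeric(1))
  expect_gt(mean(ss), 0.8)
})

test_that("latent features are deterministic, equivariant and separable", {
  fx <- twoConformerStack()
  st <- AFMStack(heights(fx$stack)[, , 1:80], pixelSize = 2)
  labels <- fx$groundTruth$labels[1:80]
  m <- trainCAE(st, testCae(epochs = 4, seed = 9))
  lfv <- extractLFV(m, st)
  expect_equal(dim(lfv), c(80, 16))
  ## duplicate frames map to identical rows
  dup <- AFMStack(heights(st)[, , c(1, 1, 2)], pixelSize = 2)
  lfvDup <- extractLFV(m, dup)
  expect_identical(lfvDup[1, ], lfvDup[2, ])
  ## permuted stack gives row-permuted features
  perm <- rev(seq_len(80))
  lfvPerm <- extractLFV(m, AFMStack(heights(st)[, , perm], pixelSize = 2))
  expect_identical(lfvPerm, lfv[perm, ])
  ## conformer groups linearly separable: a perceptron reaches 0 errors
  y <- ifelse(labels == 0, 1, -1)
  w <- numeric(ncol(lfv)); b <- 0
  for (pass in 1:200) {
    nerr <- 0
    for (i in seq_len(nrow(lfv))) {
      if (y[i] * (sum(w * lfv[i, ]) + b) <= 0) {
        w <- w + y[i] * lfv[i, ]; b <- b + y[i]; nerr <- nerr + 1
      }
    }
    if (nerr == 0) break
  }
  pred <- sign(lfv %*% w + b)
  expect_equal(sum(pred != y), 0)
  ## mismatched resolution is rejected
  expect_error(extractLFV(m, AFMStack(array(0, c(16, 16, 2)), 2)),
               "resolution")
})

test_that("locally scaled affinity matches its hand-computed example", {
  ## 3 points on a line with pairwise distances 1, 1, 2 and kScale = 1:
  ## sigma = (1, 1, 1); affinities exp(-1), exp(-4), exp(-1)
  lfv <- matrix(c(0, 1, 2), 3, 1)
  A <- localAffinity(lfv, kScale = 1)
  expect_equal(diag(A), rep(0, 3))
  expect_equal(A[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(A[2, 3], exp(-1), tolerance = 1e-12)
  expect_equal(A[1, 3], exp(-4), tolerance = 1e-12)
  expect_identical(A, t(A))
  ## coincident points have affinity 1 (duplicate fallback scale)
  A2 <- localAffinity(matrix(c(0, 0, 5), 3, 1), kScale = 1)
  expect_equal(A2[1, 2], 1)
  ## rotation invariance in feature space
  withr::with_seed(8, {
    X <- matrix(rnorm(40), 10, 4)
    Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  })
  expect_lt(max(abs(localAffinity(X, 3) - localAffinity(X %*% Q, 3))), 1e-8)
  expect_error(localAffinity(matrix(0, 5, 2), kScale = 7), "more points")
  expect_error(localAffinity(matrix(1, 9, 2), kScale = 2), "degenerate")
})

test_that("spectral clustering recovers block-diagonal affinity exactly", {
  A <- matrix(0, 10, 10)
  A[1:4, 1:4] <- 1; A[5:10, 5:10] <- 1
  diag(A) <- 0
  cl <- spectralCluster(A, 2, seed = 3)
  expect_equal(ari(cl$labels, rep(c(1, 2), c(4, 6))), 1)
  ## n = 1 and n = N degenerate cases
  expect_equal(spectralCluster(A, 1)$labels, rep(1L, 10))
  expect_equal(sort(spectralCluster(A, 10)$labels), 1:10)
  ## two well-separated Gaussian clouds in feature space
  withr::with_seed(4, {
    X <- rbind(matrix(rnorm(60, 0, 1), 30, 2),
               matrix(rnorm(60, 20, 1), 30, 2))
  })
  cl2 <- spectralCluster(localAffinity(X, 7), 2, seed = 1)
  expect_equal(ari(cl2$labels, rep(1:2, each = 30)), 1)
})

test_that("labels partition the frames with no empty cluster", {
  withr::with_seed(5, X <- matrix(rnorm(80), 40, 2))
  cl <- spectralCluster(localAffinity(X, 7), 4, seed = 2)
  expect_equal(sort(unique(cl$labels)), seq_len(cl$n))
  expect_equal(sum(lengths(cl$members)), 40)
  expect_true(all(lengths(cl$members) > 0))
})
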