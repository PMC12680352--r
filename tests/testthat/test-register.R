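testImage <- function() {
  fx <- memoFixture("regImage", function() {
    renderRecipe(pseudoProteinRecipe(1, nFrames = 1, jitterSigma = 0,
                                     seed = 2),
                 tip = TipModel(20), pixelSize = 2, extent = 32)
  })
  frameAt(fx$stack, 1)
}

test_that("rigid transforms compose, invert and fill with zero", {
  img <- testImage()
  expect_identical(applyRigid(img, rigidTransform(0, 0, 0)), img)
  ## integer-pixel translation is an exact shift with zero fill
  sh <- applyRigid(img, rigidTransform(0, 3, -2))
  expect_equal(sh[1:30, 4:32], img[3:32, 1:29], tolerance = 1e-12)
  expect_true(all(sh[, 1:3] == 0))
  expect_true(all(sh >= 0))
  ## apply then invert returns the interior to within interpolation error
  tr <- rigidTransform(17, 2.3, -1.1)
  back <- applyRigid(applyRigid(img, tr), invertRigid(tr))
  interior <- 6:27
  relErr <- mean(abs(back[interior, interior] - img[interior, interior])) /
    max(img)
  expect_lt(relErr, 0.01)
})

test_that("known rotations and translations are recovered within tolerance", {
  img <- testImage()
  t0 <- estimateRigid(img, img)
  expect_lt(abs(t0$rotationDeg), 0.1)
  expect_lt(max(abs(c(t0$dx, t0$dy))), 0.05)
  for (ang in c(30, -30)) {
    tr <- estimateRigid(applyRigid(img, rigidTransform(ang, 0, 0)), img)
    expect_lt(abs(tr$rotationDeg + ang), 2)
    expect_lt(max(abs(c(tr$dx, tr$dy))), 0.5)
  }
  tt <- estimateRigid(applyRigid(img, rigidTransform(0, 3, -2)), img)
  expect_lt(abs(tt$dx + 3), 0.5)
  expect_lt(abs(tt$dy - 2), 0.5)
  expect_lt(abs(tt$rotationDeg), 2)
  expect_error(estimateRigid(matrix(0, 8, 8), matrix(0, 8, 8)), "blank")
})

test_that("recovery degrades gracefully under 5 percent pixel noise", {
  img <- testImage()
  st <- AFMStack(applyRigid(img, rigidTransform(20, 2, -1)), pixelSize = 2)
  noisy <- frameAt(addPixelNoise(st, 0.05, seed = 3), 1)
  tr <- estimateRigid(noisy, img)
  expect_lt(abs(tr$rotationDeg + 20), 4)     # doubled tolerance at 5% noise
  expect_lt(max(abs(c(tr$dx - (-2), tr$dy - 1))), 1)
})

test_that("stack registration recovers ground-truth drift", {
  fx <- memoFixture("driftRigid60", function() {
    renderRecipe(pseudoProteinRecipe(1, nFrames = 60, jitterSigma = 0,
                                     seed = 8, aligned = FALSE),
                 tip = TipModel(20), pixelSize = 2, extent = 32)
  })
  gtt <- fx$groundTruth$transforms
  reg <- registerStack(fx$stack, 1, rotRange = 20)
  expect_equal(nFrames(reg$stack), 60)
  expect_true(all(reg$transforms[1, ] == 0))   # reference maps to itself
  ## expected transform maps frame t onto frame 1: rotation r1 - rt, and
  ## translation d1 - R(r1 - rt) dt, in pixels
  a <- (gtt$rotationDeg[1] - gtt$rotationDeg) * pi / 180
  px <- pixelSize(fx$stack)
  expDx <- (gtt$dxA[1] - (cos(a) * gtt$dxA - sin(a) * gtt$dyA)) / px
  expDy <- (gtt$dyA[1] - (sin(a) * gtt$dxA + cos(a) * gtt$dyA)) / px
  rotErr <- abs(reg$transforms$rotationDeg +
                (gtt$rotationDeg - gtt$rotationDeg[1]))
  expect_lt(max(rotErr), 2)
  expect_lt(max(abs(reg$transforms$dx - expDx)), 0.5)
  expect_lt(max(abs(reg$transforms$dy - expDy)), 0.5)
  ## registering identical frames returns identical frames
  stSame <- AFMStack(array(rep(testImage(), 3), c(32, 32, 3)), pixelSize = 2)
  regSame <- registerStack(stSame, 1)
  expect_equal(heights(regSame$stack)[, , 2], testImage(), tolerance = 1e-6)
})
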