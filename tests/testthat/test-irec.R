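test_that("silhouette selection matches the hand-computed 1D example", {
  ## points {0, 1} vs {10, 11}: s(0) = (10.5 - 1)/10.5 > s(1) = (9.5 - 1)/9.5
  lfv <- matrix(c(0, 1, 10, 11), 4, 1)
  labels <- c(1, 1, 2, 2)
  expect_equal(silhouetteSelect(c(1, 2), lfv, labels), 1)
  expect_equal(silhouetteSelect(c(3, 4), lfv, labels), 4)
  ## singleton cluster returns its only member (s = 0 convention)
  expect_equal(silhouetteSelect(3, lfv, c(1, 1, 2, 1)), 3)
  ## single-cluster labeling falls back to the medoid
  lfv2 <- matrix(c(0, 1, 10), 3, 1)
  expect_equal(silhouetteSelect(1:3, lfv2, c(1, 1, 1)), 2)
  ## tight, far-apart clusters: tie broken at the lowest index
  lfv3 <- matrix(c(0, 0, 50, 50), 4, 1)
  expect_equal(silhouetteSelect(c(1, 2), lfv3, c(1, 1, 2, 2)), 1)
})

test_that("rec retains the reference-containing cluster in both modes", {
  fx <- twoConformerDriftStack()
  st <- AFMStack(heights(fx$stack)[, , 1:60], pixelSize = 2)
  cfg <- irecConfig(cae = testCae(epochs = 3), lafm = lafmParams(2),
                    maxIter = 2)
  ## single-reference mode: all clusters reported, reference flagged
  r1 <- rec(st, refs = 5, n = 2, cfg)
  expect_length(r1$retained, 2)
  expect_length(r1$refinedRefs, 2)
  flagged <- which(vapply(r1$retained, `[[`, logical(1), "wellRegistered"))
  expect_length(flagged, 1)
  expect_true(5 %in% r1$retained[[flagged]]$frames)
  expect_true(all(vapply(seq_along(r1$retained), function(k)
    r1$refinedRefs[k] %in% r1$retained[[k]]$frames, logical(1))))
  ## multi-reference mode: each retained cluster contains its own reference
  refs <- r1$refinedRefs
  r2 <- rec(st, refs = refs, n = 2, cfg)
  for (k in 1:2) expect_true(refs[k] %in% r2$retained[[k]]$frames)
  expect_error(rec(st, refs = 999, n = 2, cfg), "out of range")
  expect_error(rec(st, refs = c(1, 2, 3), n = 2, cfg), "exactly n")
})

test_that("degenerate reference choices are visible in the audit", {
  fx <- twoConformerDriftStack()
  win <- 51:110                          # spans both conformers
  truth <- fx$groundTruth$labels[win]
  st <- AFMStack(heights(fx$stack)[, , win], pixelSize = 2)
  cfg <- irecConfig(cae = testCae(epochs = 3), lafm = lafmParams(2))
  ## duplicated reference: both registered stacks and partitions coincide,
  ## so the retained clusters overlap completely and are flagged
  rDup <- rec(st, refs = c(5, 5), n = 2, cfg)
  expect_equal(max(rDup$audit$overlapJaccard), 1)
  expect_true(rDup$audit$degenerateReferences)
  ## two distinct same-state references: the retained clusters concentrate
  ## on that state and most of the other state goes unassigned -- the audit
  ## overlap matrix is recorded for diagnosis either way
  sameState <- which(truth == 0)[1:2]
  r <- rec(st, refs = sameState, n = 2, cfg)
  expect_true(is.matrix(r$audit$overlapJaccard))
  covered <- unique(unlist(lapply(r$retained, `[[`, "frames")))
  coveredTruth <- table(factor(truth[covered], levels = 0:1))
  expect_gt(coveredTruth[["0"]], coveredTruth[["1"]])
})

test_that("irec terminates on an aligned homogeneous stack", {
  fx <- memoFixture("oneConf80", function() {
    renderRecipe(pseudoProteinRecipe(1, nFrames = 80, seed = 6),
                 tip = TipModel(20), pixelSize = 2, extent = 32)
  })
  st <- AFMStack(heights(fx$stack)[, , 1:40], pixelSize = 2)
  cfg <- irecConfig(cae = testCae(epochs = 3), lafm = lafmParams(2),
                    maxIter = 3)
  res <- irec(st, r0 = 1, n = 1, cfg)
  expect_true(res$termination %in% c("converged", "cycle", "max_iter"))
  expect_equal(sort(res$rec$retained[[1]]$frames), 1:40)
})

test_that("cycle detection guards against reference oscillation", {
  ## adversarial schedule: force maxIter high and verify the trace never
  ## revisits a reference set without being reported as a cycle
  fx <- twoConformerDriftStack()
  st <- AFMStack(heights(fx$stack)[, , 1:60], pixelSize = 2)
  cfg <- irecConfig(cae = testCae(epochs = 2), lafm = lafmParams(2),
                    maxIter = 6)
  res <- irec(st, r0 = 3, n = 2, cfg)
  expect_true(res$termination %in% c("converged", "cycle", "max_iter"))
  h <- res$trace$history
  expect_equal(length(h), length(unique(vapply(h, paste, "", collapse = ","))))
})
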