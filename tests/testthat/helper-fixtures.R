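## Shared fixtures, generated once per test run and memoized.  All fixtures
## are built in code from seeded recipes; nothing is read from disk.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(key, builder) {
  v <- get0(key, envir = .fixtureCache)
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = .fixtureCache)
  }
  v
}

## small random atom configuration for tip-geometry tests
randomAtoms <- function(n = 50, seed = 42, zRange = c(2, 9)) {
  withr::with_seed(seed, {
    AtomSet(cbind(runif(n, -12, 12), runif(n, -12, 12),
                  runif(n, zRange[1], zRange[2])),
            radii = runif(n, 1.5, 2.5))
  })
}

## 400-frame aligned two-conformer stack at 32 x 32 (heavier; memoized)
twoConformerStack <- function() {
  memoFixture("twoConf400", function() {
    renderRecipe(pseudoProteinRecipe(2, nFrames = 400, seed = 11),
                 tip = TipModel(20), pixelSize = 2, extent = 32)
  })
}

## 300-frame aligned three-conformer stack (0.45 / 0.45 / 0.10)
threeConformerStack <- function() {
  memoFixture("threeConf300", function() {
    renderRecipe(pseudoProteinRecipe(3, nFrames = 300, seed = 21),
                 tip = TipModel(20), pixelSize = 2, extent = 32)
  })
}

## 160-frame unaligned (drifting) two-conformer stack
twoConformerDriftStack <- function() {
  memoFixture("twoConfDrift160", function() {
    renderRecipe(pseudoProteinRecipe(2, nFrames = 160, seed = 31,
                                     aligned = FALSE),
                 tip = TipModel(20), pixelSize = 2, extent = 32)
  })
}

## small CAE config used throughout the clustering tests: sized for 32 x 32
## fixtures on one CPU
testCae <- function(epochs = 5, seed = 5) {
  caeConfig(latentDim = 16, convChannels = c(8, 16), epochs = epochs,
            seed = seed)
}

## adjusted Rand index between two labelings (mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
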