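test_that("axial contact height equals z + r for any tip radius and angle", {
  for (R in c(2, 20, 80)) for (th in c(10, 18, 30)) {
    expect_equal(contactHeight(5, 2, TipModel(R, th), 0), 7)
  }
})

test_that("contact height matches hand-derived sphere and cone values", {
  tip <- TipModel(20, 18)
  ## sphere regime: d = 10 < 22 cos(18 deg)
  expect_equal(contactHeight(5, 2, tip, 10), 5 + sqrt(484 - 100) - 20,
               tolerance = 1e-12)
  ## cone regime: d = 30
  th <- 18 * pi / 180
  expect_equal(contactHeight(5, 2, tip, 30),
               5 + 22 / sin(th) - 20 - 30 / tan(th), tolerance = 1e-12)
})

test_that("contact height is continuous at the sphere/cone boundary", {
  for (R in c(2, 20, 80)) {
    tip <- TipModel(R, 18)
    dB <- (R + 2) * cos(18 * pi / 180)
    gap <- abs(contactHeight(5, 2, tip, dB - 1e-9) -
               contactHeight(5, 2, tip, dB + 1e-9))
    expect_lt(gap, 1e-6)
  }
})

test_that("rendered frames match the brute-force tip-lowering oracle", {
  atoms <- randomAtoms(50, seed = 42)
  grid <- ScanGrid(-16, 16, -16, 16, 4)
  ax <- LAFMkit:::gridAxes(grid)
  for (R in c(2, 20, 80)) {
    tip <- TipModel(R)
    img <- renderFrame(atoms, tip, grid)
    ## every pixel against the sampled-surface oracle
    for (i in seq_along(ax$y)) for (j in seq_along(ax$x)) {
      o <- max(tipLowerOracle(atoms, tip, ax$x[j], ax$y[i]), 0)
      expect_lt(abs(o - img[i, j]), 1e-3)
    }
    ## and against the per-atom analytic contact (tighter tolerance)
    perAtom <- matrix(0, length(ax$y), length(ax$x))
    for (a in seq_len(nrow(atoms@coords))) {
      d <- sqrt(outer((ax$y - atoms@coords[a, 2])^2,
                      (ax$x - atoms@coords[a, 1])^2, `+`))
      perAtom <- pmax(perAtom,
                      contactHeight(atoms@coords[a, 3], atoms@radii[a], tip, d))
    }
    expect_lt(max(abs(pmax(perAtom, 0) - img)), 1e-6)
  }
})

test_that("empty or fully submerged atom sets render all-zero", {
  grid <- ScanGrid(-8, 8, -8, 8, 2)
  tip <- TipModel(20)
  empty <- AtomSet(matrix(numeric(0), 0, 3), numeric(0))
  expect_true(all(renderFrame(empty, tip, grid) == 0))
  sunk <- AtomSet(matrix(c(0, 0, -5), 1, 3), radii = 2)   # top at -3 < 0
  expect_true(all(renderFrame(sunk, tip, grid) == 0))
})

test_that("single atom centred on a pixel gives z + r there for any R", {
  grid <- ScanGrid(-8, 8, -8, 8, 2)   # pixel centres at odd integers
  atoms <- AtomSet(matrix(c(1, 1, 5), 1, 3), radii = 2)
  ax <- LAFMkit:::gridAxes(grid)
  i <- which(ax$y == 1); j <- which(ax$x == 1)
  for (R in c(2, 20, 80))
    expect_equal(renderFrame(atoms, TipModel(R), grid)[i, j], 7)
})

test_that("images are monotone in tip radius (dilation ordering)", {
  atoms <- randomAtoms(30, seed = 7)
  grid <- ScanGrid(-16, 16, -16, 16, 2)
  i2 <- renderFrame(atoms, TipModel(2), grid)
  i20 <- renderFrame(atoms, TipModel(20), grid)
  i80 <- renderFrame(atoms, TipModel(80), grid)
  expect_true(all(i20 - i2 >= -1e-12))
  expect_true(all(i80 - i20 >= -1e-12))
})

test_that("renderStack preserves frame order and attaches the code", {
  frames <- list(randomAtoms(10, seed = 1), randomAtoms(10, seed = 2))
  grid <- ScanGrid(-16, 16, -16, 16, 4)
  st <- renderStack(frames, TipModel(20), grid, code = "AC–20–4")
  expect_equal(nFrames(st), 2)
  expect_equal(frameAt(st, 2), renderFrame(frames[[2]], TipModel(20), grid))
  expect_equal(stackCode(st), "AC–20–4")
  expect_true(all(heights(st) >= 0))
})

test_that("orientSide is the identity for C and an involution for P", {
  atoms <- randomAtoms(12, seed = 3)
  expect_identical(orientSide(atoms, "C"), atoms)
  flipped <- orientSide(atoms, "P")
  back <- orientSide(flipped, "P", lowerLeafletZ = -flipped@backgroundZ)
  expect_lt(max(abs(back@coords - atoms@coords)), 1e-9)
})

test_that("periplasmic flip preserves height above its own background", {
  ## membrane slab between z = -10 (lower leaflet) and z = +10 (upper);
  ## an atom 5 A below the lower leaflet protrudes 5 A on the P side
  atoms <- AtomSet(matrix(c(3, 4, -15), 1, 3), radii = 2, backgroundZ = 10)
  flipped <- orientSide(atoms, "P", lowerLeafletZ = -10)
  expect_equal(flipped@coords[1, 3] - flipped@backgroundZ, 5)
  expect_equal(flipped@coords[1, 1], 3)    # x preserved
  expect_equal(flipped@coords[1, 2], -4)   # y mirrored
})
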