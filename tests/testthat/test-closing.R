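test_that("component-rule outlier filtering removes exactly the stray cube", {
  # compact 50-cube cluster (spacing 2 voxels, pitch 0.15 -> 0.3 um apart)
  set.seed(8)
  base <- as.matrix(expand.grid(seq(20, 28, 2), seq(20, 28, 2), c(20, 22)))
  base <- base[1:50, ]
  far <- matrix(c(60, 60, 60), 1) # > 3 um away
  cs <- makeCubeSet(rbind(base, far), side = 3, gridDim = c(70, 70, 70))
  cfg <- closingConfig(connectionRadius = 1.5, subcubePhysicalSide = 0.45)
  filt <- filterOutliers(cs, cfg)
  expect_equal(length(filt), 50L)
  expect_true(all(filt@centers[, 1] <= 28))
  # brute-force adjacency oracle agrees on the component membership
  d <- as.matrix(dist(sweep(rbind(base, far) - 0.5, 2, rep(0.15, 3), `*`)))
  expect_true(all(d[1:50, 51] > 1.5))
  # compact set with no outliers is untouched
  noOut <- filterOutliers(makeCubeSet(base, 3, c(70, 70, 70)), cfg)
  expect_equal(length(noOut), 50L)
  expect_lte(length(filt), length(cs))
  # MAD rule drops the same stray cube
  filtMad <- filterOutliers(cs, closingConfig(outlierRule = "mad",
                                              connectionRadius = 1.5,
                                              subcubePhysicalSide = 0.45))
  expect_equal(length(filtMad), 50L)
})

test_that("down-sampling keeps one cube per lattice block", {
  centers <- as.matrix(expand.grid(seq(5, 19, 2), seq(5, 19, 2), seq(5, 19, 2)))
  cs <- makeCubeSet(centers, side = 3, gridDim = c(24, 24, 24), stride = 2L)
  expect_equal(length(downsampleSet(cs, 1L)), 512L)      # identity
  ds <- downsampleSet(cs, 2L)
  expect_equal(length(ds), 64L)                          # 8x8x8 -> 4x4x4
  # retained cubes are a subset of the input
  inCenters <- apply(centers, 1, paste, collapse = ",")
  outCenters <- apply(ds@centers, 1, paste, collapse = ",")
  expect_true(all(outCenters %in% inCenters))
})

test_that("local linking equals the exact pairwise-hull oracle", {
  # two full 3^3 cubes, centres ~1 um apart at pitch 0.15 (7 voxels)
  gd <- c(24, 24, 24)
  cs <- makeCubeSet(rbind(c(8, 10, 10), c(15, 10, 10)), side = 3, gridDim = gd)
  cfg <- closingConfig(connectionRadius = 1.5, subcubePhysicalSide = 0.45)
  linked <- linkLocal(cs, cfg)
  oracle <- boxPairHullOracle(c(7, 9, 9), c(9, 11, 11),
                              c(14, 9, 9), c(16, 11, 11), gd)
  expect_identical(voxels(linked), oracle)
  # output contains the cube union
  un <- array(FALSE, gd); un[unlist(cs@voxelIndices)] <- TRUE
  expect_true(all(voxels(linked)[un]))
  # cubes farther than the connection radius stay unlinked
  csFar <- makeCubeSet(rbind(c(5, 10, 10), c(19, 10, 10)), 3, gd)
  expect_warning(bare <- linkLocal(csFar, cfg), "no cube pair")
  unFar <- array(FALSE, gd); unFar[unlist(csFar@voxelIndices)] <- TRUE
  expect_identical(voxels(bare), unFar)
})

test_that("a C-shaped arc is not bridged locally but is by the global hull", {
  # cubes on a C arc of radius 12 voxels (1.8 um), gap across the opening
  gd <- c(40, 40, 40)
  ang <- seq(40, 320, by = 20) * pi / 180
  centers <- cbind(round(20 + 12 * cos(ang)), round(20 + 12 * sin(ang)), 20)
  cs <- makeCubeSet(centers, side = 3, gridDim = gd)
  cfg <- closingConfig(connectionRadius = 0.9, subcubePhysicalSide = 0.45)
  linked <- linkLocal(cs, cfg)
  hull <- convexClose(cs)
  # the mouth of the C (around +x axis from centre) is empty after local
  # linking but filled by the global hull
  mouth <- c(28, 20, 20)
  expect_false(voxels(linked)[mouth[1], mouth[2], mouth[3]])
  expect_true(voxels(hull)[mouth[1], mouth[2], mouth[3]])
  expect_true(all(voxels(hull)[voxels(linked)]))
})

test_that("morphological closing is idempotent on smooth solids and fills cavities", {
  sphere <- sphereMask(40, 0.15, 2.2)
  cfg <- closingConfig(subcubePhysicalSide = 0.45)
  closed <- closeAndFill(sphere, cfg)
  expect_lt(mean(xor(voxels(closed), voxels(sphere))), 0.01 * mean(voxels(sphere)))
  # a fully enclosed 3^3 cavity is filled
  holed <- voxels(sphere)
  holed[19:21, 19:21, 19:21] <- FALSE
  filled <- closeAndFill(VoxelMask(holed, 0.15), cfg)
  expect_true(all(voxels(filled)[19:21, 19:21, 19:21]))
  # an open concavity with mouth wider than 2*closingRadius survives
  cup <- generatePhantom(smallSpec(targetSphericity = 0.8, riNoiseSD = 0))@nucleusMask
  closedCup <- closeAndFill(cup, cfg)
  expect_lt(sum(voxels(closedCup) & !voxels(cup)), 0.05 * sum(voxels(cup)))
})

test_that("the global hull closing is convex and contains its input", {
  b <- generatePhantom(smallSpec(targetSphericity = 0.85, riNoiseSD = 0))
  cs <- partitionSubcubes(b@nucleusMask, 3, 2)
  hull <- convexClose(cs)
  expect_gte(convexityIndex(hull), 0.98)
  un <- array(FALSE, dim(hull)); un[unlist(cs@voxelIndices)] <- TRUE
  expect_true(all(voxels(hull)[un]))
})

test_that("end-to-end segmentation meets phantom quality and nesting", {
  b <- generatePhantom(smallSpec(targetSphericity = 0.85, seed = 21))
  det <- segmentNucleus(b@tomogram, "concave", cssiConfig(seed = 3),
                        details = TRUE)
  sc <- f1Score(det$mask, b@nucleusMask)
  expect_gte(sc$f1, 0.88)
  expect_true(all(voxels(det$cellMask)[voxels(det$mask)]))
  # convex mode hides the concavity: estimated sphericity stays high
  cx <- segmentNucleus(b@tomogram, "convex", cssiConfig(seed = 3))
  expect_gte(sphericityIndex(cx), 0.93)
  expect_lt(convexityIndex(det$mask), 0.98)
  expect_gte(convexityIndex(cx), 0.98)
  # a perfect sphere: both modes agree closely
  bs <- generatePhantom(smallSpec(targetSphericity = 1, seed = 22))
  f1con <- f1Score(segmentNucleus(bs@tomogram, "concave", cssiConfig(seed = 3)),
                   bs@nucleusMask)$f1
  f1cvx <- f1Score(segmentNucleus(bs@tomogram, "convex", cssiConfig(seed = 3)),
                   bs@nucleusMask)$f1
  expect_lt(abs(f1con - f1cvx), 0.02)
})
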