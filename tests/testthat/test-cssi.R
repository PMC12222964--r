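# sharp-step, noise-free phantom: exact two-valued RI
bundleSharp <- generatePhantom(smallSpec(indenterDepth = 1.2, riNoiseSD = 0,
                                         smoothingSigma = 0, seed = 2))
# noise only, no boundary smoothing
bundleStep <- generatePhantom(smallSpec(indenterDepth = 1.2, smoothingSigma = 0,
                                        seed = 2))
bundleNoisy <- generatePhantom(smallSpec(indenterDepth = 1.2, seed = 2))

test_that("cell-mask extraction recovers the phantom cell", {
  cm <- makeCellMask(bundleSharp@tomogram)
  truthV <- sum(voxels(bundleSharp@cellMask))
  expect_lt(abs(sum(voxels(cm)) - truthV) / truthV, 0.03)
  # single component, no internal cavities
  lab <- cssi3d:::cpp_label3d(as.vector(voxels(cm)), dim(cm), 26L)
  expect_equal(attr(lab, "n_components"), 1L)
  expect_identical(voxels(cm), cssi3d:::fillHoles(voxels(cm)))
  blank <- RITomogram(array(1.334, c(16, 16, 16)), 0.2)
  expect_error(makeCellMask(blank), "no cell")
})

test_that("the low-RI initial guess is rough but anchored in the nucleus", {
  tomo <- bundleSharp@tomogram
  cm <- makeCellMask(tomo)
  # percentile below the nucleus volume fraction (~20%) of this phantom
  g <- nucleusInitialGuess(tomo, cm, 15)
  expect_true(all(voxels(cm)[voxels(g)])) # subset of the cell
  truth <- voxels(bundleSharp@nucleusMask)
  # noiseless guess stays within the 2-voxel-dilated true nucleus
  dil <- cssi3d:::cpp_edt3d(as.vector(truth), dim(truth), c(1, 1, 1)) <= 4 + 1e-9
  expect_true(all(dil[voxels(g)]))
  expect_gte(sum(voxels(g) & truth) / sum(truth), 0.5)
  # with continuous (noisy) RI values a vanishing percentile leaves too few
  # voxels to anchor anything
  expect_error(nucleusInitialGuess(bundleNoisy@tomogram,
                                   makeCellMask(bundleNoisy@tomogram), 0.001),
               "guessPercentile")
})

test_that("the reference cube sits at the interior-most point of the guess", {
  sphere <- sphereMask(32, 0.2, 2.4)
  ref <- makeReferenceCube(sphere, 5)
  expect_true(max(abs(ref$center - 16.5)) <= 1)
  expect_lte(length(ref$voxelIndices), 125L)
  expect_gte(length(ref$voxelIndices), 1L)
  # cup guess: centre inside the guess body, not in the concavity void
  cup <- bundleSharp@nucleusMask
  refc <- makeReferenceCube(cup, 5)
  expect_true(voxels(cup)[matrix(refc$center, 1)])
  # thin guess: shrink with warning, error below side 3
  slab <- array(FALSE, c(20, 20, 20)); slab[3:18, 3:18, 9:11] <- TRUE
  expect_warning(r2 <- makeReferenceCube(VoxelMask(slab, 0.2), 9), "shrunk")
  expect_lt(r2$side, 9)
  sheet <- array(FALSE, c(20, 20, 20)); sheet[3:18, 3:18, 10] <- TRUE
  expect_error(suppressWarnings(makeReferenceCube(VoxelMask(sheet, 0.2), 9)),
               "side")
})

test_that("sub-cube partition matches a brute-force lattice count", {
  solid <- array(FALSE, c(36, 36, 36)); solid[4:33, 4:33, 4:33] <- TRUE
  mask <- VoxelMask(solid, 0.2)
  part <- partitionSubcubes(mask, side = 9, stride = 9)
  # brute force: lattice of centres half a side in from the bbox corner,
  # inside the mask, cube clipped, >= 25% occupancy
  cnt <- 0L
  for (i in seq.int(8, 29, 9)) for (j in seq.int(8, 29, 9))
    for (k in seq.int(8, 29, 9)) {
      if (!solid[i, j, k]) next
      rng <- function(c) max(1, c - 4):min(36, c + 4)
      if (sum(solid[rng(i), rng(j), rng(k)]) >= 0.25 * 729) cnt <- cnt + 1L
    }
  expect_equal(length(part), cnt)
  expect_true(all(unlist(part@voxelIndices) %in% which(solid)))
  # a cube as large as the bounding box gives exactly one cube
  one <- partitionSubcubes(mask, side = 29, stride = 5)
  expect_equal(length(one), 1L)
  # halving the stride never decreases the count
  n4 <- length(partitionSubcubes(mask, side = 9, stride = 4))
  n2 <- length(partitionSubcubes(mask, side = 9, stride = 2))
  expect_gte(n2, n4)
  expect_error(partitionSubcubes(mask, side = 35, stride = 5), "extent")
})

test_that("rank-sum similarity p-values match stats::wilcox.test", {
  set.seed(31)
  for (i in 1:20) {
    x <- round(rnorm(30, 0, 1), i %% 3) # induce ties sometimes
    y <- round(rnorm(50, 0.3 * (i %% 4), 1), i %% 3)
    ours <- similarityPValue(x, y)
    ref <- suppressWarnings(wilcox.test(y, x, exact = FALSE, correct = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  ident <- rnorm(40)
  expect_gte(similarityPValue(ident, ident), 0.99)
  expect_error(similarityPValue(rnorm(10), rnorm(30)), "20")
})

test_that("compartment RI samples are distinguished; the null is calibrated", {
  set.seed(5)
  nuc <- rnorm(100, 1.350, 0.004)
  cyt <- rnorm(100, 1.370, 0.004)
  p <- similarityPValue(nuc, cyt)
  expect_lt(p, 1e-6)
  # permutation oracle: observed rank-sum is extreme among label shuffles
  pooled <- c(nuc, cyt)
  obs <- sum(rank(pooled)[101:200])
  perm <- replicate(2000, {
    idx <- sample(200, 100)
    sum(rank(pooled)[idx])
  })
  expect_lt(mean(abs(perm - mean(perm)) >= abs(obs - mean(perm))), 5e-4 + 1e-12)
  # null calibration: p approximately uniform
  set.seed(99)
  ref <- sort(rnorm(200))
  tests <- lapply(1:1000, function(i) rnorm(40))
  pv <- cssi3d:::cpp_ranksum_batch(ref, tests)
  expect_lt(abs(mean(pv < 0.05) - 0.05), 0.02)
})

test_that("statistical selection recovers the nucleus and is deterministic", {
  tomo <- bundleStep@tomogram # sharp compartments, plain RI noise
  cm <- makeCellMask(tomo)
  g <- nucleusInitialGuess(tomo, cm, 15)
  cfg <- cssiConfig(seed = 4)
  ref <- makeReferenceCube(g, cfg$referenceSide)
  part <- partitionSubcubes(cm, cfg$subcubeSide, cfg$stride)
  sel <- selectSimilar(tomo, ref, part, cfg)
  un <- array(FALSE, dim(cm))
  un[unlist(sel@voxelIndices)] <- TRUE
  truth <- voxels(bundleStep@nucleusMask)
  expect_gte(sum(un & truth) / sum(truth), 0.9)   # recall
  expect_gte(sum(un & truth) / sum(un), 0.8)      # precision
  expect_true(all(voxels(cm)[un]))                # union inside the cell
  sel2 <- selectSimilar(tomo, ref, part, cfg)
  expect_identical(sel@voxelIndices, sel2@voxelIndices)
})
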