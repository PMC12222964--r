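test_that("F1 scoring matches its arithmetic and a brute-force confusion count", {
  a <- VoxelMask(array(TRUE, c(3, 3, 3)), 1)
  expect_equal(f1Score(a, a)$f1, 1)
  pred <- array(FALSE, c(4, 4, 4)); truth <- array(FALSE, c(4, 4, 4))
  pred[1:10] <- TRUE                       # 10 predicted
  truth[3:12] <- TRUE                      # TP = 8, FP = 2, FN = 2
  sc <- f1Score(VoxelMask(pred, 1), VoxelMask(truth, 1))
  expect_equal(c(sc$TP, sc$FP, sc$FN), c(8, 2, 2))
  expect_equal(sc$f1, 0.8)
  disj <- array(FALSE, c(4, 4, 4)); disj[40:50] <- TRUE
  expect_equal(f1Score(VoxelMask(disj, 1), VoxelMask(truth, 1))$f1, 0)
  # random masks: exact agreement with direct counting
  set.seed(12)
  for (i in 1:5) {
    p <- array(runif(1000) < 0.4, c(10, 10, 10))
    t <- array(runif(1000) < 0.4, c(10, 10, 10))
    sc <- f1Score(VoxelMask(p, 1), VoxelMask(t, 1))
    TP <- sum(p & t); FP <- sum(p & !t); FN <- sum(!p & t)
    expect_identical(c(sc$TP, sc$FP, sc$FN), c(TP, FP, FN))
    expect_equal(sc$f1, 2 * TP / (2 * TP + FP + FN))
  }
  expect_error(f1Score(a, VoxelMask(array(TRUE, c(4, 4, 4)), 1)), "differ")
})

test_that("the concavity VOI brackets the carved region of a cup phantom", {
  b <- generatePhantom(smallSpec(targetSphericity = 0.82, riNoiseSD = 0))
  voi <- concavityVOI(b)
  nm <- voxels(b@nucleusMask)
  dm <- dim(nm)
  # hull-minus-nucleus voxels all inside the box
  shell <- array(cssi3d:::cpp_shell6(as.vector(nm), dm), dm)
  hull <- array(cssi3d:::cpp_voxel_hull((which(shell, arr.ind = TRUE) - 1) * 1.0,
                                        dm), dm)
  gap <- which(hull & !nm, arr.ind = TRUE)
  expect_true(all(sweep(gap, 2, voi["lo", ], `>`) &
                  sweep(gap, 2, voi["hi", ], `<=`)))
  # box is local: smaller than the nucleus bounding box
  nbb <- apply(which(nm, arr.ind = TRUE), 2, range)
  expect_lt(prod(voi["hi", ] - voi["lo", ]), prod(nbb[2, ] - nbb[1, ] + 1))
  sphereB <- generatePhantom(smallSpec(indenterDepth = 0, riNoiseSD = 0))
  expect_error(concavityVOI(sphereB), "no concavity")
  # localized F1 differs from global on an eroded prediction
  ero <- VoxelMask(array(cssi3d:::cpp_edt3d(as.vector(!nm), dm,
                                            pitch(b@nucleusMask)) > 0.36, dm),
                   pitch(b@nucleusMask))
  expect_false(isTRUE(all.equal(f1Score(ero, b@nucleusMask)$f1,
                                f1Score(ero, b@nucleusMask, voi)$f1)))
})

test_that("Fisher discriminant ranking follows its closed form and symmetries", {
  a <- data.frame(f = c(rep(0, 5), 1e-9), g = rnorm(6))
  expect_equal(fdrRank(a, a)$fdr, c(0, 0), tolerance = 1e-18)
  x <- data.frame(v = c(-1, 0, 1, -1, 0, 1, -1, 0, 1, 0))   # mean 0, sd ~0.816
  y <- data.frame(v = x$v + 2)
  r <- fdrRank(x, y)
  expect_equal(r$fdr, 4 / (2 * sd(x$v)^2), tolerance = 1e-12)
  # population exchange symmetry
  expect_equal(fdrRank(y, x)$fdr, r$fdr, tolerance = 1e-12)
  # invariance under common affine rescaling
  xs <- data.frame(v = 3 * x$v - 7); ys <- data.frame(v = 3 * y$v - 7)
  expect_equal(fdrRank(xs, ys)$fdr, r$fdr, tolerance = 1e-12)
  expect_equal(r$p_value, t.test(x$v, y$v)$p.value, tolerance = 1e-12)
  # zero variance in both populations: NA with a warning
  z1 <- data.frame(c1 = rep(1, 5), ok = rnorm(5))
  z2 <- data.frame(c1 = rep(1, 5), ok = rnorm(5, 2))
  expect_warning(rz <- fdrRank(z1, z2), "zero variance")
  expect_true(is.na(rz$fdr[rz$feature == "c1"]))
  expect_error(fdrRank(x[1:2, , drop = FALSE], y), "at least 3")
})

test_that("seeded region growing matches the flood-fill oracle and handles noise", {
  bNoiseless <- generatePhantom(smallSpec(indenterDepth = 1.2, riNoiseSD = 0,
                                          smoothingSigma = 0, seed = 2))
  tomo <- bNoiseless@tomogram
  cm <- makeCellMask(tomo)
  g <- nucleusInitialGuess(tomo, cm, 15)
  rg <- regionGrowing(tomo, cm, g, tolerance = 0.01) # half the 0.02 contrast
  expect_gte(f1Score(rg, bNoiseless@nucleusMask)$f1, 0.95)
  # tolerance 0 on the sharp-step phantom: the connected RI level set of the
  # seed (26-connectivity flood fill at equal values)
  rg0 <- regionGrowing(tomo, cm, g, tolerance = 0)
  vox <- voxels(tomo)
  gidx <- which(voxels(g)) # same guess as above (percentile 15)
  seed <- gidx[which.min(abs(vox[gidx] - median(vox[gidx])))]
  level <- array(vox == vox[seed] & voxels(cm), dim(vox))
  lab <- cssi3d:::cpp_label3d(as.vector(level), dim(vox), 26L)
  oracle <- array(lab == lab[seed], dim(vox))
  expect_identical(voxels(rg0), oracle)
  # heavy noise degrades region growing below concave CSSI
  bNoisy <- suppressWarnings( # sd 0.02 noise strays outside the RI range
    generatePhantom(smallSpec(indenterDepth = 1.2, riNoiseSD = 0.02, seed = 2)))
  cmN <- makeCellMask(bNoisy@tomogram)
  gN <- nucleusInitialGuess(bNoisy@tomogram, cmN, 25)
  f1rg <- f1Score(regionGrowing(bNoisy@tomogram, cmN, gN, 0.01),
                  bNoisy@nucleusMask)$f1
  f1cssi <- f1Score(segmentNucleus(bNoisy@tomogram, "concave",
                                   cssiConfig(seed = 2)),
                    bNoisy@nucleusMask)$f1
  expect_lt(f1rg, f1cssi)
})

test_that("the recovery experiment is reproducible and carries all columns", {
  rec1 <- recoveryExperiment(levels = c(0.85, 1), algorithms = c("rg"),
                             nRepeats = 1, seed = 5, spec = smallSpec())
  rec2 <- recoveryExperiment(levels = c(0.85, 1), algorithms = c("rg"),
                             nRepeats = 1, seed = 5, spec = smallSpec())
  expect_identical(rec1, rec2)
  expect_true(all(c("level", "algorithm", "truth_sphericity", "f1",
                    "f1_local", "est_sphericity") %in% names(rec1)))
  expect_true(is.na(rec1$f1_local[rec1$level == 1]))
  expect_false(any(is.na(rec1$f1_local[rec1$level < 1])))
})
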