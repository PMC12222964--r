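uniformTomo <- function(ri, n = 6, pitch = 0.5) {
  suppressWarnings(RITomogram(array(ri, c(n, n, n)), pitch))
}
fullMask <- function(n = 6, pitch = 0.5) VoxelMask(array(TRUE, c(n, n, n)), pitch)

test_that("dry-mass density evaluates the refractive-increment formula", {
  expect_equal(dryMassDensity(uniformTomo(1.334), fullMask()), 0, tolerance = 1e-9)
  expect_equal(dryMassDensity(uniformTomo(1.372), fullMask()), 0.2, tolerance = 1e-9)
  expect_equal(dryMassDensity(uniformTomo(1.391), fullMask()), 0.3, tolerance = 1e-9)
  expect_error(dryMassDensity(uniformTomo(1.37), VoxelMask(array(FALSE, c(6, 6, 6)), 0.5)),
               "empty")
})

test_that("volume and surface match closed forms and scale dimensionally", {
  sph <- sphereMask(48, 0.1, 2) # r = 20 voxels
  vs <- volumeAndSurface(sph)
  expect_lt(abs(vs$volume - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.01)
  expect_lt(abs(vs$surface - 4 * pi * 4) / (4 * pi * 4), 0.02)
  single <- VoxelMask(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)), c(3, 3, 3)), 1)
  expect_equal(volumeAndSurface(single)$volume, 1)
  # doubling the pitch scales V by 8 and S by 4
  sph2 <- VoxelMask(voxels(sph), 0.2)
  vs2 <- volumeAndSurface(sph2)
  expect_equal(vs2$volume / vs$volume, 8, tolerance = 1e-12)
  expect_equal(vs2$surface / vs$surface, 4, tolerance = 1e-9)
})

test_that("sphericity: sphere near 1, hemisphere at its closed form, monotone in depth", {
  expect_gte(sphericityIndex(sphereMask(48, 0.1, 2)), 0.97)
  n <- 100; p <- 0.1
  hemi <- sphereArray(n, p, 4) &
    (array(rep((seq_len(n) - 0.5) * p, each = n * n), c(n, n, n)) >= n / 2 * p)
  expect_lt(abs(sphericityIndex(VoxelMask(hemi, p)) - 4^(2 / 3) / 3), 0.02)
  sp <- smallSpec()
  sph <- vapply(c(0, 0.8, 1.6, 2.4), function(d)
    sphericityIndex(VoxelMask(cssi3d:::phantomNucleusMask(sp, d), sp$pitch)),
    numeric(1))
  expect_true(all(diff(sph) < 0))
})

test_that("convexity index: convex solids at 1, notched cube at its closed form", {
  cube <- array(FALSE, c(16, 16, 16)); cube[4:13, 4:13, 4:13] <- TRUE
  expect_gte(convexityIndex(VoxelMask(cube, 1)), 0.99)
  notched <- cube; notched[9:13, 9:13, 9:13] <- FALSE
  # hull = cube minus a corner tetrahedron of volume 5^3/6
  expect_lt(abs(convexityIndex(VoxelMask(notched, 1)) - 875 / (1000 - 125 / 6)),
            0.02)
  # hull closing can only raise convexity
  cs <- partitionSubcubes(VoxelMask(notched, 1), 3, 2)
  expect_gte(convexityIndex(convexClose(cs)) + 1e-9,
             convexityIndex(VoxelMask(notched, 1)))
})

test_that("concavity radius: near 1 for a sphere, lower for a cup, shell is 6-connected boundary", {
  sph <- sphereMask(100, 0.1, 4) # r = 40 voxels
  expect_lt(abs(normalizedConcavityRadius(sph) - 1), 0.03)
  sp <- smallSpec()
  r0 <- normalizedConcavityRadius(VoxelMask(cssi3d:::phantomNucleusMask(sp, 0), sp$pitch))
  r15 <- normalizedConcavityRadius(VoxelMask(cssi3d:::phantomNucleusMask(sp, 1.5), sp$pitch))
  expect_lt(r15, r0)
  # shell oracle on a small mask: voxels with a 6-neighbour outside
  m <- sphereArray(12, 1, 4)
  shell <- array(cssi3d:::cpp_shell6(as.vector(m), dim(m)), dim(m))
  oracle <- array(FALSE, dim(m))
  for (i in 1:12) for (j in 1:12) for (k in 1:12) {
    if (!m[i, j, k]) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    edge <- any(apply(nb, 1, function(q)
      any(q < 1 | q > 12) || !m[q[1], q[2], q[3]]))
    oracle[i, j, k] <- edge
  }
  expect_identical(shell, oracle)
})

test_that("centroid distance: concentric zero, calibrated offset, translation invariant", {
  n <- 60; p <- 0.1
  cell <- sphereMask(n, p, 2.5)
  nucC <- sphereMask(n, p, 1)
  expect_lt(normalizedCentroidDistance(cell, nucC), 0.02)
  # nucleus of equivalent radius 1 um displaced by 1 um -> value 1
  nucOff <- sphereMask(n, p, 1, center = c(n / 2 * p + 1, n / 2 * p, n / 2 * p))
  expect_lt(abs(normalizedCentroidDistance(cell, nucOff) - 1), 0.03)
  # joint translation leaves the value unchanged
  sh <- c(5, -3, 2)
  shift <- function(m) {
    out <- array(FALSE, dim(m))
    src <- voxels(m)
    out[(1:(n - 5)) + 5, 1:(n - 3), (1:(n - 2)) + 2] <-
      src[1:(n - 5), 4:n, 1:(n - 2)]
    VoxelMask(out, p)
  }
  expect_equal(normalizedCentroidDistance(shift(cell), shift(nucOff)),
               normalizedCentroidDistance(cell, nucOff), tolerance = 1e-9)
})

test_that("feature records compose the individual descriptors exactly", {
  b <- generatePhantom(smallSpec(indenterDepth = 1.2, seed = 9))
  rec <- featureRecord(b@tomogram, b@cellMask, b@nucleusMask)
  expect_identical(names(rec), names(cssi3d:::featureUnits))
  expect_equal(rec$nucleus_dry_mass_density,
               dryMassDensity(b@tomogram, b@nucleusMask), tolerance = 1e-12)
  cyto <- VoxelMask(voxels(b@cellMask) & !voxels(b@nucleusMask), pitch(b@cellMask))
  expect_equal(rec$cytoplasm_dry_mass_density,
               dryMassDensity(b@tomogram, cyto), tolerance = 1e-12)
  vsC <- volumeAndSurface(b@cellMask); vsN <- volumeAndSurface(b@nucleusMask)
  expect_equal(rec$nucleus_cell_volume_ratio, vsN$volume / vsC$volume,
               tolerance = 1e-12)
  # dry-mass additivity: cell contrast * V_C = cyto * V_cyt + nucleus * V_N
  lhs <- rec$cell_dry_mass_density * vsC$volume
  rhs <- rec$cytoplasm_dry_mass_density * maskVolume(cyto) +
    rec$nucleus_dry_mass_density * vsN$volume
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # nucleus outside the cell is rejected
  expect_error(featureRecord(b@tomogram, b@nucleusMask, b@cellMask), "subset")
})
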