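test_that("NRRD volume round-trip is lossless and carries metadata", {
  vox <- array(1.334 + 0.04 * runif(6 * 5 * 4), c(6, 5, 4))
  tomo <- RITomogram(vox, pitch = c(0.12, 0.12, 0.12), mediumRI = 1.337)
  f <- tempfile(fileext = ".nrrd")
  writeVolume(tomo, f)
  back <- loadVolume(f)
  # one float32 quantization on write; a second cycle is bit-identical
  expect_equal(voxels(back), voxels(tomo), tolerance = 1e-6)
  f2 <- tempfile(fileext = ".nrrd")
  writeVolume(back, f2)
  expect_identical(voxels(loadVolume(f2)), voxels(back))
  expect_identical(pitch(back), c(0.12, 0.12, 0.12))
  expect_identical(mediumRI(back), 1.337)
  # sidecar stores pitch without unit conversion
  side <- jsonlite::fromJSON(paste0(f, ".json"))
  expect_identical(side$pitch_um, c(0.12, 0.12, 0.12))
  expect_error(writeVolume(tomo, f), "overwrite")
})

test_that("TIFF volume round-trip restores RI through the sidecar", {
  vox <- array(1.334 + 0.04 * runif(8 * 8 * 3), c(8, 8, 3))
  tomo <- RITomogram(vox, pitch = 0.15)
  f <- tempfile(fileext = ".tif")
  writeVolume(tomo, f)
  back <- loadVolume(f)
  expect_equal(voxels(back), voxels(tomo), tolerance = 1e-6)
  expect_identical(pitch(back), rep(0.15, 3))
})

test_that("degenerate volumes are rejected with a clear message", {
  # 2D TIFF (single page)
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), f)
  expect_error(loadVolume(f), "must be 3D")
  expect_error(loadVolume(tempfile(fileext = ".nrrd")), "does not exist")
  # NRRD without pitch information
  f2 <- tempfile(fileext = ".nrrd")
  cssi3d:::writeNRRD(runif(8), c(2, 2, 2), f2, type = "float")
  expect_error(loadVolume(f2), "pitch")
})

test_that("mask round-trip maps 0/255 to logical and checks the grid", {
  m <- VoxelMask(array(runif(4^3) > 0.5, c(4, 4, 4)), 0.2)
  for (ext in c(".nrrd", ".tif")) {
    f <- tempfile(fileext = ext)
    writeMask(m, f)
    back <- loadMask(f, pitch = 0.2)
    expect_identical(voxels(back), voxels(m))
  }
  # stored NRRD values are exactly {0, 255}
  f <- tempfile(fileext = ".nrrd")
  writeMask(m, f)
  raw <- cssi3d:::readNRRD(f)
  expect_setequal(unique(raw$data), c(0L, 255L))
  tomo96 <- RITomogram(array(1.334, c(6, 6, 6)), 0.2)
  expect_error(loadMask(f, reference = tomo96), "does not match")
})

test_that("feature tables round-trip at full precision in panel order", {
  rec <- do.call(rbind, list(
    data.frame(cell_dry_mass_density = 0.11223344556677,
               cytoplasm_dry_mass_density = 0.1, nucleus_dry_mass_density = 0.2,
               nucleus_cell_volume_ratio = 1 / 3, nucleus_cell_surface_ratio = 0.5,
               normalized_nucleus_cell_distance = 0.25,
               nucleus_convexity_index = 0.9, normalized_concavity_radius = 0.8,
               nucleus_sphericity_index = 0.95),
    data.frame(cell_dry_mass_density = 0.2, cytoplasm_dry_mass_density = 0.15,
               nucleus_dry_mass_density = pi / 10,
               nucleus_cell_volume_ratio = 0.4, nucleus_cell_surface_ratio = 0.6,
               normalized_nucleus_cell_distance = 0.1,
               nucleus_convexity_index = 0.99, normalized_concavity_radius = 0.97,
               nucleus_sphericity_index = 0.98)))
  f <- tempfile(fileext = ".csv")
  writeFeatureTable(rec, f)
  lines <- readLines(f)
  expect_length(lines, 4L) # units comment + header + 2 rows
  expect_match(lines[1], "units")
  back <- readFeatureTable(f)
  expect_identical(names(back), names(cssi3d:::featureUnits))
  expect_equal(as.matrix(back), as.matrix(rec), tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_error(writeFeatureTable(rec[0, ], tempfile()), "empty")
})

test_that("YAML configuration overrides constructor defaults section-wise", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("cssi:", "  alpha: 0.01", "  subcubeSide: 5",
               "otf:", "  na: 1.2"), f)
  cfg <- loadConfig(f)
  expect_equal(cfg$cssi$alpha, 0.01)
  expect_equal(cfg$cssi$subcubeSide, 5L)
  expect_equal(cfg$otf$na, 1.2)
  expect_equal(cfg$closing$closingRadius, closingConfig()$closingRadius)
})
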