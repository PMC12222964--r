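# Fixtures are built in code; nothing is read from disk.

# logical sphere mask on an n^3 grid (pitch um, radius um, centre um)
sphereArray <- function(n, pitch, radius, center = rep(n / 2 * pitch, 3)) {
  x <- (seq_len(n) - 0.5) * pitch
  d2 <- outer(outer((x - center[1])^2, (x - center[2])^2, `+`),
              (x - center[3])^2, `+`)
  d2 <= radius^2
}

sphereMask <- function(n, pitch, radius, center = rep(n / 2 * pitch, 3)) {
  VoxelMask(sphereArray(n, pitch, radius, center), pitch)
}

# small, fast phantom: 64^3, nucleus radius ~14 voxels
smallSpec <- function(...) {
  phantomSpec(gridShape = 64, pitch = 0.18, cellRadius = 4.4,
              nucleusRadius = 2.6, indenterRadius = 2.0, ...)
}

# hand-built SubCubeSet from full (unclipped) cubes at given centres
makeCubeSet <- function(centers, side, gridDim, pitch = 0.15, stride = 1L) {
  keep <- array(TRUE, gridDim)
  vox <- lapply(seq_len(nrow(centers)), function(r)
    cssi3d:::subCube(as.integer(centers[r, ]), as.integer(side), keep))
  new("SubCubeSet", centers = as.matrix(centers), voxelIndices = vox,
      side = as.integer(side), stride = as.integer(stride),
      gridDim = as.integer(gridDim), pitch = rep(pitch, 3),
      provenance = "partition")
}

# exact point-in-hull oracle for the union of two axis-aligned boxes:
# conv(A u B) = union over lambda of (1-lambda) A + lambda B, giving per-axis
# linear interval constraints in lambda
boxPairHullOracle <- function(loA, hiA, loB, hiB, gridDim) {
  out <- array(FALSE, gridDim)
  for (k in seq_len(gridDim[3])) for (j in seq_len(gridDim[2]))
    for (i in seq_len(gridDim[1])) {
      v <- c(i, j, k)
      lamLo <- 0; lamHi <- 1
      ok <- TRUE
      for (a in 1:3) {
        # (1-l) loA + l loB <= v <= (1-l) hiA + l hiB
        # lower bound: loA + l (loB - loA) <= v
        d <- loB[a] - loA[a]; c0 <- v[a] - loA[a]
        if (abs(d) < 1e-12) { if (c0 < -1e-9) { ok <- FALSE; break } }
        else if (d > 0) lamHi <- min(lamHi, c0 / d)
        else lamLo <- max(lamLo, c0 / d)
        d <- hiB[a] - hiA[a]; c0 <- v[a] - hiA[a]
        if (abs(d) < 1e-12) { if (c0 > 1e-9) { ok <- FALSE; break } }
        else if (d > 0) lamLo <- max(lamLo, c0 / d)
        else lamHi <- min(lamHi, c0 / d)
      }
      out[i, j, k] <- ok && lamLo <= lamHi + 1e-9
    }
  out
}
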