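# CSSI core: cell mask, low-RI nucleus initial guess, reference cube,
# sub-cube partition and iterated statistical selection.

#' CSSI configuration
#'
#' Tuning parameters of the statistical sub-cube clustering. The sub-cube
#' side sets the boundary resolution of the intermediate nucleus set: a cube
#' straddling the nucleus surface is accepted only while its contaminated
#' fraction stays below the detection threshold of the rank-sum test
#' (roughly `z_alpha / (0.5 * sqrt(12 * side^3))` for a large reference), so
#' larger cubes stop further from the surface. The default side 3 (27 voxels,
#' above the 20-value minimum of the test) tolerates ~20% contamination and
#' follows the boundary to within about one voxel; side 9 would stand off by
#' several voxels and visibly erode a 20-voxel nucleus. All parameters are
#' exposed: the algorithm family, not one setting, is the deliverable.
#'
#' @param guessPercentile percentage (0, 50) of lowest within-cell RI values
#'   forming the nucleus initial guess.
#' @param referenceSide odd integer >= 3; side (voxels) of the reference cube.
#' @param subcubeSide odd integer >= 3; side (voxels) of the partition cubes.
#' @param stride lattice step (voxels) of the partition; overlap allowed.
#' @param testName `"ranksum"` (Wilcoxon, default) or `"ks"`
#'   (Kolmogorov-Smirnov).
#' @param alpha significance level: cubes with p >= alpha (equality not
#'   rejected) are accepted into the nucleus set.
#' @param maxIterations cap on reference re-estimation rounds.
#' @param refSubsample cap on the pooled reference sample size per iteration.
#' @param boundaryErosion voxels peeled off the cell surface before the
#'   initial guess and the partition. The medium-cytoplasm partial-volume
#'   ramp contains a sub-shell whose RI median coincides with the nucleus;
#'   a location test cannot reject it, so that shell must not enter the
#'   candidate set. Nuclei are always separated from the membrane by
#'   cytoplasm, so the exclusion is safe.
#' @param seed RNG seed for the reference subsampling.
#' @return A validated list of class `cssiConfig`.
#' @export
cssiConfig <- function(guessPercentile = 25, referenceSide = 5L,
                       subcubeSide = 3L, stride = 2L,
                       testName = c("ranksum", "ks"), alpha = 0.05,
                       maxIterations = 10L, refSubsample = 2000L,
                       boundaryErosion = 2, seed = 1L) {
  testName <- match.arg(testName)
  cfg <- list(guessPercentile = guessPercentile,
              referenceSide = as.integer(referenceSide),
              subcubeSide = as.integer(subcubeSide),
              stride = as.integer(stride), testName = testName,
              alpha = alpha, maxIterations = as.integer(maxIterations),
              refSubsample = as.integer(refSubsample),
              boundaryErosion = boundaryErosion, seed = as.integer(seed))
  stopifnot(cfg$guessPercentile > 0, cfg$guessPercentile < 50,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$subcubeSide >= 3L, cfg$subcubeSide %% 2L == 1L,
            cfg$referenceSide >= 3L, cfg$referenceSide %% 2L == 1L,
            cfg$stride >= 1L, cfg$stride <= cfg$subcubeSide)
  class(cfg) <- "cssiConfig"
  cfg
}

#' Segment the cell shell from a single-cell tomogram
#'
#' Thresholds at `mediumRI + backgroundMargin`, keeps the largest connected
#' component and fills internal cavities.
#'
#' @param tomo an [RITomogram-class] containing one cell on a homogeneous
#'   medium background.
#' @param backgroundMargin RI offset above the medium (default 0.006).
#' @return A [VoxelMask-class] (single connected component, no cavities).
#' @export
makeCellMask <- function(tomo, backgroundMargin = 0.006) {
  thr <- mediumRI(tomo) + backgroundMargin
  raw <- voxels(tomo) >= thr
  if (!any(raw))
    stop(sprintf("no cell found: no voxel above RI threshold %.4f", thr))
  mask <- fillHoles(largestComponent(raw, 26L))
  VoxelMask(mask, pitch(tomo))
}

#' Low-RI nucleus initial guess
#'
#' Selects the voxels inside the cell whose RI lies at or below the
#' `guessPercentile`-th percentile of the within-cell RI distribution and
#' keeps the largest connected component. The guess is deliberately rough: a
#' plain RI threshold is not a reliable nucleus segmentation, it only anchors
#' the reference cube.
#'
#' @param tomo an [RITomogram-class].
#' @param cellMask the cell shell ([makeCellMask()]).
#' @param guessPercentile percentage in (0, 50).
#' @param boundaryErosion voxels peeled off the cell surface before
#'   thresholding: the partial-volume ramp between medium and cytoplasm
#'   passes through nucleus-level RI values and would otherwise contaminate
#'   the guess with a surface shell.
#' @return A [VoxelMask-class], always a subset of `cellMask`.
#' @export
nucleusInitialGuess <- function(tomo, cellMask, guessPercentile = 25,
                                boundaryErosion = 2) {
  cm <- voxels(cellMask)
  if (!any(cm)) stop("cell mask is empty")
  if (boundaryErosion > 0) {
    d2 <- cpp_edt3d(as.vector(!cm), dim(cm), c(1, 1, 1))
    interior <- array(d2 > boundaryErosion^2, dim(cm))
    if (sum(interior) >= 1000L) cm <- interior
  }
  vals <- voxels(tomo)[cm]
  thr <- quantile(vals, guessPercentile / 100, names = FALSE)
  guess <- cm & (voxels(tomo) <= thr)
  guess <- largestComponent(guess, 26L)
  if (sum(guess) < 100L)
    stop(sprintf(
      "initial guess has only %d voxels; increase guessPercentile", sum(guess)))
  VoxelMask(guess, pitch(tomo))
}

subCube <- function(center, side, keepMask) {
  h <- (side - 1L) %/% 2L
  dm <- dim(keepMask)
  rng <- lapply(1:3, function(a) max(1L, center[a] - h):min(dm[a], center[a] + h))
  block <- keepMask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  ind <- which(block, arr.ind = TRUE)
  if (nrow(ind) == 0L) return(integer(0))
  ind[, 1] <- ind[, 1] + rng[[1]][1] - 1L
  ind[, 2] <- ind[, 2] + rng[[2]][1] - 1L
  ind[, 3] <- ind[, 3] + rng[[3]][1] - 1L
  as.integer(ind[, 1] + dm[1] * (ind[, 2] - 1L) + dm[1] * dm[2] * (ind[, 3] - 1L))
}

#' Reference cube of the concave CSSI initialization
#'
#' Centres a cube of side `referenceSide` on the interior-most voxel of the
#' initial guess (the voxel maximizing the distance to the guess boundary,
#' after a 1-voxel closing that heals noise raggedness), clipped to the
#' closed guess. For a cup-shaped guess this lands inside the guess body,
#' never in the concavity void; for a convex nucleus it coincides with the
#' classic central-voxel initialization.
#'
#' @param guess a non-empty [VoxelMask-class].
#' @param referenceSide odd integer; shrunk (with a warning) where the guess
#'   is thinner than requested; guesses too thin to yield 20 reference
#'   voxels are an error.
#' @return A list with `center` (voxel triple), `side`, and `voxelIndices`
#'   (1-based linear indices, clipped to the closed guess).
#' @export
makeReferenceCube <- function(guess, referenceSide = 5L) {
  g <- voxels(guess)
  if (!any(g)) stop("empty guess")
  dm <- dim(g)
  # regularize: a 1-voxel ball closing plus hole fill turns a noise-ragged
  # guess into a solid from which an interior point is meaningful
  dil <- cpp_edt3d(as.vector(g), as.integer(dm), c(1, 1, 1)) <= 1 + 1e-9
  ero <- cpp_edt3d(as.vector(!array(dil, dm)), as.integer(dm), c(1, 1, 1)) > 1 + 1e-9
  solid <- fillHoles(array(ero, dm))
  if (!any(solid)) solid <- g
  d2 <- cpp_edt3d(as.vector(!solid), as.integer(dm), c(1, 1, 1))
  d2[!solid] <- 0
  best <- which.max(d2) # deterministic: first maximum in linear order
  side <- as.integer(referenceSide)
  fit <- as.integer(2L * floor(sqrt(d2[best])) + 1L)
  if (fit < side) {
    warning(sprintf("reference side shrunk from %d to %d (thin guess)", side, fit))
    side <- max(fit, 3L)
  }
  center <- as.integer(arrayInd(best, dm))
  vox <- subCube(center, side, solid)
  if (length(vox) < 20L)
    stop("initial guess is too thin for a reference cube (side < 3 or under 20 voxels)")
  list(center = center, side = side, voxelIndices = vox)
}

#' Partition the cell volume into sub-cubes
#'
#' Lays a regular lattice of cube centres (step `stride`) over the cell-mask
#' bounding box, keeps centres inside the mask, clips each cube to the mask
#' and drops cubes retaining fewer than 25% of `side^3` voxels.
#'
#' @param cellMask a [VoxelMask-class].
#' @param side odd cube side (voxels).
#' @param stride lattice step (voxels), `stride <= side`.
#' @return A [SubCubeSet-class] with provenance `"partition"`.
#' @export
partitionSubcubes <- function(cellMask, side = 5L, stride = 2L) {
  side <- as.integer(side); stride <- as.integer(stride)
  stopifnot(stride >= 1L, stride <= side)
  cm <- voxels(cellMask)
  dm <- dim(cm)
  ind <- which(cm, arr.ind = TRUE)
  lo <- apply(ind, 2, min); hi <- apply(ind, 2, max)
  if (any(hi - lo + 1L < side))
    stop(sprintf("sub-cube side %d exceeds the mask extent (%s)", side,
                 paste(hi - lo + 1L, collapse = "x")))
  # cubes tile the bounding box: first centre half a side in from the corner
  h <- (side - 1L) %/% 2L
  gseq <- lapply(1:3, function(a) seq.int(lo[a] + h, hi[a] - h, by = stride))
  centers <- as.matrix(expand.grid(gseq[[1]], gseq[[2]], gseq[[3]]))
  colnames(centers) <- NULL
  inside <- cm[centers]
  centers <- centers[inside, , drop = FALSE]
  vox <- lapply(seq_len(nrow(centers)), function(r) subCube(centers[r, ], side, cm))
  keep <- lengths(vox) >= 0.25 * side^3
  new("SubCubeSet", centers = centers[keep, , drop = FALSE],
      voxelIndices = vox[keep], side = side, stride = stride,
      gridDim = as.integer(dm), pitch = pitch(cellMask),
      provenance = "partition")
}

#' Two-sample similarity p-value
#'
#' Two-sided test of distribution equality between a reference RI sample and
#' a test sample; a higher p-value means more similar. The default rank-sum
#' test uses the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param referenceValues,testValues numeric samples of at least 20 values
#'   each.
#' @param testName `"ranksum"` or `"ks"`.
#' @return p-value in \[0, 1\].
#' @export
similarityPValue <- function(referenceValues, testValues,
                             testName = c("ranksum", "ks")) {
  testName <- match.arg(testName)
  if (length(referenceValues) < 20L || length(testValues) < 20L)
    stop("both samples need at least 20 values")
  if (testName == "ranksum") {
    cpp_ranksum_batch(sort(as.numeric(referenceValues)),
                      list(as.numeric(testValues)))[1]
  } else {
    suppressWarnings(ks.test(testValues, referenceValues)$p.value)
  }
}

#' Select the sub-cubes statistically similar to the reference
#'
#' Iterative clustering: every sub-cube is tested against the reference
#' sample; cubes whose p-value is at least `alpha` (equality not rejected)
#' are accepted; the reference sample is re-formed from the pooled accepted
#' voxels (capped at `refSubsample` values, seeded subsampling) and the
#' procedure repeats until the accepted set is stable or `maxIterations` is
#' reached.
#'
#' @param tomo an [RITomogram-class].
#' @param reference reference cube from [makeReferenceCube()].
#' @param partition a [SubCubeSet-class] from [partitionSubcubes()].
#' @param cfg a [cssiConfig()].
#' @return A [SubCubeSet-class] with provenance `"intermediate"`, plus
#'   attribute `iterations` (accepted-cube count per iteration).
#' @export
selectSimilar <- function(tomo, reference, partition, cfg = cssiConfig()) {
  vox <- voxels(tomo)
  refValues <- vox[reference$voxelIndices]
  cubeValues <- lapply(partition@voxelIndices, function(ix) vox[ix])
  accepted <- integer(0)
  history <- integer(0)
  withSeed(cfg$seed, {
    for (it in seq_len(cfg$maxIterations)) {
      p <- if (cfg$testName == "ranksum") {
        cpp_ranksum_batch(sort(as.numeric(refValues)), cubeValues)
      } else {
        vapply(cubeValues, function(v)
          suppressWarnings(ks.test(v, refValues)$p.value), numeric(1))
      }
      newAccepted <- which(p >= cfg$alpha)
      history <- c(history, length(newAccepted))
      if (length(newAccepted) == 0L) {
        if (it == 1L)
          stop("no sub-cube accepted; increase alpha or improve the initial guess")
        break
      }
      if (identical(newAccepted, accepted)) { accepted <- newAccepted; break }
      accepted <- newAccepted
      # re-form the reference from the accepted cubes most similar to the
      # current reference (highest p first) up to the subsample cap; pooling
      # *all* accepted voxels instead lets boundary contamination inflate the
      # reference spread and drift it into the cytoplasm
      ord <- accepted[order(-p[accepted], accepted)]
      pool <- integer(0)
      for (ci in ord) {
        if (length(pool) >= cfg$refSubsample) break
        pool <- union(pool, partition@voxelIndices[[ci]])
      }
      refValues <- vox[pool]
      if (length(refValues) > cfg$refSubsample)
        refValues <- sample(refValues, cfg$refSubsample)
    }
  })
  out <- new("SubCubeSet", centers = partition@centers[accepted, , drop = FALSE],
             voxelIndices = partition@voxelIndices[accepted],
             side = partition@side, stride = partition@stride,
             gridDim = partition@gridDim, pitch = partition@pitch,
             provenance = "intermediate")
  attr(out, "iterations") <- history
  out
}
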