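# Concavity-preserving closing of the intermediate sub-cube set, and the
# global convex-hull closing of the original (convex) CSSI as a baseline.

#' Closing configuration
#'
#' @param outlierRule `"component"` (keep the largest centre-adjacency
#'   component; parameter-free given `connectionRadius`) or `"mad"` (drop
#'   cubes whose centre distance from the set's spatial median exceeds
#'   `median + madK * MAD`; for sparse sets).
#' @param madK MAD multiplier of the `"mad"` rule.
#' @param downsampleFactor integer >= 1; one cube kept per `factor^3` lattice
#'   block.
#' @param connectionRadius um; radius of the connection sphere used for both
#'   centre adjacency and local pairwise linking. Must exceed the physical
#'   sub-cube side; default 2x that side.
#' @param closingRadius um; ball radius of the final morphological closing.
#'   Must stay below half the smallest concavity mouth to be preserved.
#' @param subcubePhysicalSide um; physical side of the sub-cubes the
#'   configuration will be applied to (used for validation and the
#'   `connectionRadius` default).
#' @return A validated list of class `closingConfig`.
#' @export
closingConfig <- function(outlierRule = c("component", "mad"), madK = 3,
                          downsampleFactor = 1L, connectionRadius = NULL,
                          closingRadius = 0.4, subcubePhysicalSide = 0.75) {
  outlierRule <- match.arg(outlierRule)
  if (is.null(connectionRadius)) connectionRadius <- 2 * subcubePhysicalSide
  cfg <- list(outlierRule = outlierRule, madK = madK,
              downsampleFactor = as.integer(downsampleFactor),
              connectionRadius = connectionRadius,
              closingRadius = closingRadius,
              subcubePhysicalSide = subcubePhysicalSide)
  stopifnot(cfg$downsampleFactor >= 1L, cfg$closingRadius > 0,
            cfg$connectionRadius > cfg$subcubePhysicalSide)
  class(cfg) <- "closingConfig"
  cfg
}

centersPhysical <- function(set) {
  sweep(set@centers - 0.5, 2L, set@pitch, `*`)
}

replaceCubes <- function(set, keep, provenance) {
  out <- new("SubCubeSet", centers = set@centers[keep, , drop = FALSE],
             voxelIndices = set@voxelIndices[keep], side = set@side,
             stride = set@stride, gridDim = set@gridDim, pitch = set@pitch,
             provenance = provenance)
  out
}

#' Remove outlier sub-cubes from the intermediate nucleus set
#'
#' @param intermediate a non-empty [SubCubeSet-class].
#' @param cfg a [closingConfig()].
#' @return A [SubCubeSet-class] with provenance `"filtered"`.
#' @export
filterOutliers <- function(intermediate, cfg = closingConfig()) {
  n <- length(intermediate)
  if (n == 0L) stop("intermediate set is empty")
  ctr <- centersPhysical(intermediate)
  if (cfg$outlierRule == "component") {
    d <- as.matrix(dist(ctr))
    adj <- d <= cfg$connectionRadius
    comp <- integer(n)
    cur <- 0L
    for (s in seq_len(n)) {
      if (comp[s] > 0L) next
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    sizes <- tabulate(comp)
    keep <- comp == which.max(sizes)
  } else {
    med <- apply(ctr, 2, median)
    dmed <- sqrt(rowSums(sweep(ctr, 2L, med)^2))
    madv <- mad(dmed, constant = 1)
    keep <- dmed <= median(dmed) + cfg$madK * max(madv, .Machine$double.eps)
  }
  if (!any(keep)) stop("outlier filtering removed every sub-cube")
  replaceCubes(intermediate, keep, "filtered")
}

#' Down-sample a sub-cube set on a coarser lattice
#'
#' Keeps one cube per `factor^3` block of the centre lattice (the cube
#' closest to the block centre; ties broken by input order), reducing the
#' pair count of the local linking.
#'
#' @param filtered a [SubCubeSet-class].
#' @param factor integer >= 1 (1 = identity).
#' @return A [SubCubeSet-class] with provenance `"downsampled"`.
#' @export
downsampleSet <- function(filtered, factor = 2L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L || length(filtered) <= 1L)
    return(replaceCubes(filtered, seq_len(length(filtered)), "downsampled"))
  blockLen <- factor * filtered@stride
  ctr <- filtered@centers
  origin <- apply(ctr, 2, min)
  block <- floor(sweep(ctr, 2L, origin) / blockLen)
  blockId <- block[, 1] + 1e4 * block[, 2] + 1e8 * block[, 3]
  blockCenter <- sweep((block + 0.5) * blockLen, 2L, origin, `+`)
  d2 <- rowSums((ctr - blockCenter)^2)
  ord <- order(blockId, d2, seq_len(nrow(ctr)))
  keepRows <- ord[!duplicated(blockId[ord])]
  replaceCubes(filtered, sort(keepRows), "downsampled")
}

#' Locally link sub-cubes into a 3D nucleus polygonal
#'
#' For every pair of cubes whose centres lie within `connectionRadius`, the
#' convex hull of the union of the two cubes' voxels is rasterized into the
#' output (local pairwise hulls only, never a global hull), preserving
#' surface concavities wider than the connection sphere. The result always
#' contains the union of the cube voxels.
#'
#' @param downsampled a [SubCubeSet-class] with at least 2 cubes.
#' @param cfg a [closingConfig()].
#' @return A [VoxelMask-class] (the nucleus polygonal).
#' @export
linkLocal <- function(downsampled, cfg = closingConfig()) {
  if (length(downsampled) < 2L) stop("need at least 2 sub-cubes to link")
  res <- cpp_link_pairs(downsampled@voxelIndices,
                        downsampled@centers - 0.5,
                        downsampled@gridDim, downsampled@pitch,
                        cfg$connectionRadius)
  if (res$npairs == 0L)
    warning("no cube pair within connectionRadius; returning the bare cube union")
  VoxelMask(array(res$mask, downsampled@gridDim), downsampled@pitch)
}

#' Morphological closing, hole filling and component selection
#'
#' Closes the nucleus polygonal with a Euclidean ball of radius
#' `closingRadius` (exact distance-transform dilation/erosion), fills
#' enclosed cavities and keeps the largest connected component. An open
#' surface concavity with mouth wider than `2 * closingRadius` is not a
#' topological hole and survives.
#'
#' @param polygonal a non-empty [VoxelMask-class].
#' @param cfg a [closingConfig()].
#' @return A [VoxelMask-class] (the final nucleus).
#' @export
closeAndFill <- function(polygonal, cfg = closingConfig()) {
  m <- voxels(polygonal)
  if (!any(m)) stop("empty mask")
  dm <- dim(m)
  r2 <- cfg$closingRadius^2
  dil <- cpp_edt3d(as.vector(m), as.integer(dm), pitch(polygonal)) <= r2
  ero <- cpp_edt3d(as.vector(!array(dil, dm)), as.integer(dm), pitch(polygonal)) > r2
  closed <- array(ero, dm)
  closed <- fillHoles(closed)
  closed <- largestComponent(closed, 26L)
  VoxelMask(closed, pitch(polygonal))
}

#' Global convex-hull closing (convex-CSSI baseline)
#'
#' Rasterizes the global convex hull of all sub-cube voxels: the closing of
#' the original convex CSSI, in which surface concavities are lost.
#'
#' @param intermediate a non-empty [SubCubeSet-class].
#' @return A [VoxelMask-class].
#' @export
convexClose <- function(intermediate) {
  if (length(intermediate) < 1L) stop("empty sub-cube set")
  dm <- intermediate@gridDim
  un <- array(FALSE, dm)
  un[unlist(intermediate@voxelIndices, use.names = FALSE)] <- TRUE
  shell <- array(cpp_shell6(as.vector(un), as.integer(dm)), dm)
  pts <- which(shell, arr.ind = TRUE) - 1L
  hull <- array(cpp_voxel_hull(pts * 1.0, as.integer(dm)), dm)
  VoxelMask(hull | un, intermediate@pitch)
}

#' End-to-end nucleus segmentation
#'
#' Runs the full pipeline: cell mask, mode-specific initialization (concave:
#' interior-most voxel of the low-RI guess; convex: cell-mask centroid),
#' statistical sub-cube selection, then either the concavity-preserving
#' closing (outlier filter, down-sampling, local linking, morphological
#' closing) or the global convex-hull closing. The final mask is intersected
#' with the cell mask.
#'
#' @param tomo a single-cell [RITomogram-class].
#' @param mode `"concave"` (default) or `"convex"`.
#' @param cssiCfg a [cssiConfig()].
#' @param closingCfg a [closingConfig()]; its `subcubePhysicalSide` is
#'   derived from `cssiCfg` when left `NULL`.
#' @param details return intermediate stages as well?
#' @return A [VoxelMask-class], or (with `details = TRUE`) a list with
#'   elements `mask`, `cellMask`, `guess`, `intermediate`, `filtered`,
#'   `downsampled`, `iterations`.
#' @examples
#' \donttest{
#' bun <- generatePhantom(phantomSpec(gridShape = 64, pitch = 0.18,
#'                                    cellRadius = 4.4, nucleusRadius = 2.6,
#'                                    indenterRadius = 2, indenterDepth = 1.2))
#' nuc <- segmentNucleus(bun@tomogram)
#' f1Score(nuc, bun@nucleusMask)$f1
#' }
#' @export
segmentNucleus <- function(tomo, mode = c("concave", "convex"),
                           cssiCfg = cssiConfig(), closingCfg = NULL,
                           details = FALSE) {
  mode <- match.arg(mode)
  if (is.null(closingCfg))
    closingCfg <- closingConfig(
      subcubePhysicalSide = cssiCfg$subcubeSide * max(pitch(tomo)))
  cellMask <- stopWithStage("cell_mask", makeCellMask(tomo))
  # Both modes share the concavity-safe low-RI initialization: a reference at
  # the cell-volume centre (the classic choice for convex nuclei) falls into
  # the carved void of a deep cup and derails the baseline, so the modes
  # differ only in their closing.
  guess <- stopWithStage("initial_guess",
                         nucleusInitialGuess(tomo, cellMask, cssiCfg$guessPercentile,
                                             cssiCfg$boundaryErosion))
  reference <- stopWithStage("reference_cube",
                             makeReferenceCube(guess, cssiCfg$referenceSide))
  # candidate sub-cubes come from the cell interior: the partial-volume
  # surface shell mimics the nucleus RI median and must stay out
  searchMask <- cellMask
  if (cssiCfg$boundaryErosion > 0) {
    d2 <- cpp_edt3d(as.vector(!voxels(cellMask)), dim(cellMask), c(1, 1, 1))
    interior <- array(d2 > cssiCfg$boundaryErosion^2, dim(cellMask))
    if (sum(interior) >= 1000L)
      searchMask <- VoxelMask(interior, pitch(cellMask))
  }
  partition <- stopWithStage("partition",
                             partitionSubcubes(searchMask, cssiCfg$subcubeSide, cssiCfg$stride))
  intermediate <- stopWithStage("select_similar",
                                selectSimilar(tomo, reference, partition, cssiCfg))
  if (mode == "concave") {
    filtered <- stopWithStage("filter_outliers", filterOutliers(intermediate, closingCfg))
    down <- stopWithStage("downsample", downsampleSet(filtered, closingCfg$downsampleFactor))
    polygonal <- stopWithStage("link_local", linkLocal(down, closingCfg))
    final <- stopWithStage("close_and_fill", closeAndFill(polygonal, closingCfg))
  } else {
    # the global hull is unusable without outlier removal: one stray accepted
    # cube inflates it towards the whole cell
    filtered <- stopWithStage("filter_outliers", filterOutliers(intermediate, closingCfg))
    down <- NULL
    final <- stopWithStage("convex_close", convexClose(filtered))
  }
  out <- VoxelMask(voxels(final) & voxels(cellMask), pitch(tomo))
  out <- VoxelMask(largestComponent(voxels(out), 26L), pitch(tomo))
  if (!details) return(out)
  list(mask = out, cellMask = cellMask, guess = guess,
       intermediate = intermediate, filtered = filtered, downsampled = down,
       iterations = attr(intermediate, "iterations"))
}
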