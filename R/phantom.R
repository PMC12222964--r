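# Numerical cell phantom: sphere-within-sphere RI model with a
# spherical-indenter concavity carved into the nucleus.

#' Phantom specification
#'
#' Parameters of the synthetic single-cell tomogram used for validating the
#' nucleus segmentation. The cell is a sphere of cytoplasm containing a
#' nucleus sphere whose cup-like concavity is carved by subtracting an
#' indenter sphere; `indenterDepth` is how deep the indenter surface
#' penetrates the nucleus surface (0 = perfect sphere). When
#' `targetSphericity` is given, the depth is solved by bisection instead.
#'
#' Default RI values follow the ordering observed in holographic tomograms of
#' leukaemia cells (nucleus below cytoplasm, nucleolus above) with magnitudes
#' typical of quantitative phase imaging; all are exposed here.
#'
#' @param gridShape voxels per axis (scalar or length 3).
#' @param pitch voxel pitch in um (scalar or length 3).
#' @param cellRadius,nucleusRadius um.
#' @param nucleusOffset um displacement of the nucleus centre from the cell
#'   centre (length 3).
#' @param indenterRadius um; sphere subtracted from the nucleus.
#' @param indenterDepth um penetration of the indenter into the nucleus.
#' @param indenterDirection unit direction from nucleus centre towards the
#'   indenter centre.
#' @param targetSphericity optional value in (0, 1] overriding
#'   `indenterDepth`.
#' @param riMedium,riCytoplasm,riNucleus,riNucleolus dimensionless RI means.
#' @param riNoiseSD dimensionless; Gaussian RI noise inside the cell.
#' @param nucleolusRadius um (0 disables the nucleolus, the default).
#' @param smoothingSigma um; Gaussian blur of compartment boundaries.
#' @param seed integer RNG seed.
#' @return A validated list of class `phantomSpec`.
#' @examples
#' sp <- phantomSpec(gridShape = 48, pitch = 0.3, cellRadius = 5,
#'                   nucleusRadius = 3)
#' @export
phantomSpec <- function(gridShape = 96, pitch = 0.15,
                        cellRadius = 5, nucleusRadius = 3,
                        nucleusOffset = c(0, 0, 0),
                        indenterRadius = 2.2, indenterDepth = 0,
                        indenterDirection = c(1, 0, 0),
                        targetSphericity = NULL,
                        riMedium = 1.334, riCytoplasm = 1.370,
                        riNucleus = 1.350, riNucleolus = 1.385,
                        riNoiseSD = 0.004, nucleolusRadius = 0,
                        smoothingSigma = 0.15, seed = 1L) {
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  spec <- list(gridShape = as.integer(gridShape), pitch = as.numeric(pitch),
               cellRadius = cellRadius, nucleusRadius = nucleusRadius,
               nucleusOffset = as.numeric(nucleusOffset),
               indenterRadius = indenterRadius, indenterDepth = indenterDepth,
               indenterDirection = indenterDirection / sqrt(sum(indenterDirection^2)),
               targetSphericity = targetSphericity,
               riMedium = riMedium, riCytoplasm = riCytoplasm,
               riNucleus = riNucleus, riNucleolus = riNucleolus,
               riNoiseSD = riNoiseSD, nucleolusRadius = nucleolusRadius,
               smoothingSigma = smoothingSigma, seed = as.integer(seed))
  stopifnot(all(spec$pitch > 0), spec$cellRadius > 0,
            spec$nucleusRadius > 0, spec$indenterRadius > 0,
            spec$indenterDepth >= 0, length(spec$nucleusOffset) == 3L)
  if (!is.null(spec$targetSphericity) &&
      (spec$targetSphericity <= 0 || spec$targetSphericity > 1))
    stop("targetSphericity must lie in (0, 1]")
  if (spec$nucleolusRadius > 0 &&
      !(spec$riNucleus < spec$riCytoplasm && spec$riCytoplasm < spec$riNucleolus))
    stop("RI ordering violated: need riNucleus < riCytoplasm < riNucleolus")
  class(spec) <- "phantomSpec"
  spec
}

# squared distance field (um^2) from a centre (um), on the spec grid
distance2Field <- function(spec, center) {
  gs <- spec$gridShape; p <- spec$pitch
  dx <- ((seq_len(gs[1]) - 0.5) * p[1] - center[1])^2
  dy <- ((seq_len(gs[2]) - 0.5) * p[2] - center[2])^2
  dz <- ((seq_len(gs[3]) - 0.5) * p[3] - center[3])^2
  outer(outer(dx, dy, `+`), dz, `+`)
}

phantomCenters <- function(spec) {
  gridCenter <- spec$gridShape * spec$pitch / 2
  nucleusCenter <- gridCenter + spec$nucleusOffset
  list(cell = gridCenter, nucleus = nucleusCenter)
}

# ground-truth nucleus mask for a given indenter depth (fast path used by
# the sphericity solver)
phantomNucleusMask <- function(spec, depth = spec$indenterDepth) {
  ctr <- phantomCenters(spec)
  nuc <- distance2Field(spec, ctr$nucleus) <= spec$nucleusRadius^2
  if (depth > 0) {
    indCenter <- ctr$nucleus + spec$indenterDirection *
      (spec$nucleusRadius + spec$indenterRadius - depth)
    nuc <- nuc & !(distance2Field(spec, indCenter) <= spec$indenterRadius^2)
  }
  nuc
}

#' Solve the indenter depth reaching a target nucleus sphericity
#'
#' Bisection on the indenter penetration depth until the mesh-measured
#' sphericity of the carved ground-truth nucleus mask is within
#' `tol` of `targetSphericity`. Sphericity decreases monotonically with
#' depth over the feasible range.
#'
#' @param targetSphericity value in (0, 1].
#' @param spec a [phantomSpec()].
#' @param tol sphericity tolerance of the bisection (default 0.005).
#' @return Depth in micrometres.
#' @export
solveIndenterDepth <- function(targetSphericity, spec, tol = 0.005) {
  stopifnot(targetSphericity > 0, targetSphericity <= 1)
  mask0 <- phantomNucleusMask(spec, 0)
  s0 <- sphericityIndex(VoxelMask(mask0, spec$pitch))
  # mesh sphericity of a digitized sphere may slightly exceed 1
  if (targetSphericity >= min(s0, 1) - tol) return(0)
  # maximum depth: indenter removes at most half the nucleus volume
  v0 <- sum(mask0)
  dmax <- spec$nucleusRadius + spec$indenterRadius
  lo <- 0; hi <- spec$indenterDepth
  hi <- dmax
  # shrink hi to the deepest feasible depth
  repeat {
    vh <- sum(phantomNucleusMask(spec, hi))
    if (vh >= 0.5 * v0) break
    hi <- hi * 0.8
    if (hi < spec$pitch[1]) stop("no feasible indenter depth; enlarge the indenter")
  }
  sh <- sphericityIndex(VoxelMask(phantomNucleusMask(spec, hi), spec$pitch))
  if (sh > targetSphericity + tol)
    stop(sprintf(
      "target sphericity %.3f unreachable (deepest feasible carving reaches %.3f); use a larger indenterRadius",
      targetSphericity, sh))
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    sm <- sphericityIndex(VoxelMask(phantomNucleusMask(spec, mid), spec$pitch))
    if (abs(sm - targetSphericity) <= tol) return(mid)
    if (sm > targetSphericity) lo <- mid else hi <- mid
    if (hi - lo < 1e-4) break
  }
  (lo + hi) / 2
}

#' Generate a numerical cell phantom
#'
#' Builds a synthetic RI tomogram (medium background, cytoplasm and nucleus
#' mean RIs, optional nucleolus, Gaussian boundary smoothing, Gaussian RI
#' noise inside the cell) together with ground-truth masks. Deterministic for
#' a fixed `spec$seed`.
#'
#' @param spec a [phantomSpec()].
#' @return A [PhantomBundle-class].
#' @examples
#' bun <- generatePhantom(phantomSpec(gridShape = 48, pitch = 0.3,
#'                                    cellRadius = 5, nucleusRadius = 3,
#'                                    indenterDepth = 1.2))
#' bun@achievedSphericity
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  depth <- spec$indenterDepth
  if (!is.null(spec$targetSphericity))
    depth <- solveIndenterDepth(spec$targetSphericity, spec)
  ctr <- phantomCenters(spec)
  gs <- spec$gridShape; p <- spec$pitch
  # feasibility: nucleus inside cell, cell inside grid
  if (sqrt(sum(spec$nucleusOffset^2)) + spec$nucleusRadius > spec$cellRadius)
    stop("infeasible geometry: nucleus sphere is clipped by the cell boundary")
  if (any(ctr$cell - spec$cellRadius < p) || any(ctr$cell + spec$cellRadius > gs * p - p))
    stop("infeasible geometry: cell sphere is clipped by the grid")
  cell <- distance2Field(spec, ctr$cell) <= spec$cellRadius^2
  nucSphere <- distance2Field(spec, ctr$nucleus) <= spec$nucleusRadius^2
  nuc <- phantomNucleusMask(spec, depth)
  if (sum(nuc) < 0.5 * sum(nucSphere))
    stop("infeasible geometry: indenter removes more than 50% of the nucleus volume")
  nucleolus <- NULL
  ri <- array(spec$riMedium, gs)
  ri[cell] <- spec$riCytoplasm
  ri[nuc] <- spec$riNucleus
  if (spec$nucleolusRadius > 0) {
    nucleolus <- distance2Field(spec, ctr$nucleus) <= spec$nucleolusRadius^2
    nucleolus <- nucleolus & nuc
    ri[nucleolus] <- spec$riNucleolus
  }
  if (spec$smoothingSigma > 0) {
    ri <- array(cpp_gauss3d(as.vector(ri), as.integer(gs), spec$smoothingSigma / p), gs)
  }
  if (spec$riNoiseSD > 0) {
    noise <- withSeed(spec$seed, rnorm(sum(cell), 0, spec$riNoiseSD))
    ri[cell] <- ri[cell] + noise
  }
  tomo <- RITomogram(ri, pitch = p, mediumRI = spec$riMedium)
  nucMask <- VoxelMask(nuc, p)
  spec$indenterDepth <- depth
  new("PhantomBundle",
      tomogram = tomo,
      cellMask = VoxelMask(cell, p),
      nucleusMask = nucMask,
      nucleolusMask = if (is.null(nucleolus)) NULL else VoxelMask(nucleolus, p),
      achievedSphericity = sphericityIndex(nucMask),
      spec = unclass(spec))
}

#' 2D reprojection of a binary mask
#'
#' Rotates the binary volume by Euler angles (about x, then y, then z, in the
#' physical frame), re-thresholds the trilinear interpolation at 0.5, sums
#' along the projection axis and normalizes the image to its maximum.
#'
#' @param mask a non-empty [VoxelMask-class].
#' @param rotation numeric(3), Euler angles in degrees about the x, y and z
#'   axes (applied in that order).
#' @param axis projection axis, `"x"`, `"y"` or `"z"` (default `"z"`, the
#'   optical axis).
#' @return A numeric matrix in \[0, 1\] with maximum exactly 1.
#' @export
reproject <- function(mask, rotation = c(0, 0, 0), axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  if (!any(voxels(mask))) stop("empty mask")
  ang <- rotation * pi / 180
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rz %*% Ry %*% Rx
  dm <- dim(mask)
  rot <- cpp_rotate_trilinear(as.double(as.vector(voxels(mask))), as.integer(dm),
                              pitch(mask), as.vector(t(R)))
  rot <- array(rot >= 0.5, dm)
  proj <- switch(axis,
                 x = apply(rot, c(2, 3), sum),
                 y = apply(rot, c(1, 3), sum),
                 z = apply(rot, c(1, 2), sum))
  m <- max(proj)
  if (m == 0) stop("rotated mask is empty after re-thresholding")
  proj / m
}
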