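# Per-cell biophysical and 3D morphological features.

#' Morphometry constants
#'
#' @param alpha refractive increment in mL/g (default 0.19).
#' @param n0 medium refractive index (default 1.334, water).
#' @return A validated list of class `morphometryConstants`.
#' @export
morphometryConstants <- function(alpha = 0.19, n0 = 1.334) {
  stopifnot(alpha > 0)
  structure(list(alpha = alpha, n0 = n0), class = "morphometryConstants")
}

#' Dry-mass density of a masked region
#'
#' The non-aqueous mass per unit volume, `(mean RI - n0) / alpha`, in
#' pg/um^3.
#'
#' @param tomo an [RITomogram-class].
#' @param mask a non-empty [VoxelMask-class].
#' @param constants a [morphometryConstants()].
#' @return Density in pg/um^3.
#' @examples
#' tomo <- suppressWarnings(RITomogram(array(1.372, c(4, 4, 4)), 0.1))
#' mask <- VoxelMask(array(TRUE, c(4, 4, 4)), 0.1)
#' dryMassDensity(tomo, mask) # (1.372 - 1.334) / 0.19 = 0.2
#' @export
dryMassDensity <- function(tomo, mask, constants = morphometryConstants()) {
  m <- voxels(mask)
  if (!any(m)) stop("empty mask")
  (mean(voxels(tomo)[m]) - constants$n0) / constants$alpha
}

#' Volume and surface area of a mask
#'
#' Volume is voxel count times voxel volume. Surface area is measured on the
#' 0.5-level isosurface of the Gaussian-smoothed (sigma = 1 voxel) indicator
#' field, triangulated by marching tetrahedra; voxel-face counting would
#' overestimate curved surfaces by tens of percent.
#'
#' @param mask a non-empty [VoxelMask-class].
#' @return A list with `volume` (um^3) and `surface` (um^2).
#' @export
volumeAndSurface <- function(mask) {
  m <- voxels(mask)
  if (!any(m)) stop("empty mask")
  p <- pitch(mask)
  V <- sum(m) * prod(p)
  dm <- dim(m)
  # pad so surfaces close even at the grid border
  pad <- array(0, dm + 2L)
  pad[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- m
  sm <- cpp_gauss3d(as.vector(pad), as.integer(dim(pad)), c(1, 1, 1))
  S <- cpp_mt_area(sm, as.integer(dim(pad)), p, 0.5)
  list(volume = V, surface = S)
}

#' Sphericity index
#'
#' Surface area of the volume-equivalent sphere over the actual surface
#' area: `pi^(1/3) (6V)^(2/3) / S`. 1 for a perfect sphere, lower for any
#' other shape; decreases with the depth of a surface concavity.
#'
#' @inheritParams volumeAndSurface
#' @return Dimensionless value in (0, 1] (up to ~2% discretization excess).
#' @export
sphericityIndex <- function(mask) {
  vs <- volumeAndSurface(mask)
  pi^(1 / 3) * (6 * vs$volume)^(2 / 3) / vs$surface
}

#' Convexity index
#'
#' Volume of the mask over the volume of its voxelized convex hull
#' (`V_N / V_H`); 1 for a convex object.
#'
#' @inheritParams volumeAndSurface
#' @return Dimensionless value in (0, 1] (up to ~2% discretization
#'   tolerance).
#' @export
convexityIndex <- function(mask) {
  m <- voxels(mask)
  if (!any(m)) stop("empty mask")
  dm <- dim(m)
  shell <- array(cpp_shell6(as.vector(m), as.integer(dm)), dm)
  pts <- (which(shell, arr.ind = TRUE) - 1L) * 1.0
  hull <- cpp_voxel_hull(pts, as.integer(dm))
  sum(m) / max(sum(hull), sum(m))
}

#' Normalized concavity radius
#'
#' Distance from the mask centroid to the closest point of the mask shell
#' (6-connectivity boundary voxels), normalized to the equivalent radius
#' `R = (3V / 4 pi)^(1/3)`. 1 for a centred sphere; a deeper concavity
#' brings the shell closer to the centroid and lowers the value.
#'
#' @inheritParams volumeAndSurface
#' @return Dimensionless value.
#' @export
normalizedConcavityRadius <- function(mask) {
  m <- voxels(mask)
  if (!any(m)) stop("empty mask")
  p <- pitch(mask)
  dm <- dim(m)
  shell <- array(cpp_shell6(as.vector(m), as.integer(dm)), dm)
  ctr <- maskCentroid(m, p)
  sp <- indexToPhysical(which(shell, arr.ind = TRUE), p)
  dmin <- sqrt(min(rowSums(sweep(sp, 2L, ctr)^2)))
  R <- (3 * sum(m) * prod(p) / (4 * pi))^(1 / 3)
  dmin / R
}

#' Normalized nucleus-cell centroid distance
#'
#' Euclidean distance between the cell and nucleus voxel-count centroids,
#' normalized to the nucleus equivalent radius.
#'
#' @param cellMask,nucleusMask non-empty [VoxelMask-class] objects on the
#'   same grid.
#' @return Dimensionless value.
#' @export
normalizedCentroidDistance <- function(cellMask, nucleusMask) {
  cm <- voxels(cellMask); nm <- voxels(nucleusMask)
  if (!any(cm) || !any(nm)) stop("empty mask")
  checkSameGrid(cm, nm, "mask grids")
  p <- pitch(cellMask)
  d <- sqrt(sum((maskCentroid(cm, p) - maskCentroid(nm, p))^2))
  R <- (3 * sum(nm) * prod(p) / (4 * pi))^(1 / 3)
  d / R
}

#' Compute the nine-feature record of one cell
#'
#' Dry-mass densities of cell, cytoplasm (cell minus nucleus) and nucleus;
#' nucleus-cell volume and surface ratios; normalized nucleus-cell centroid
#' distance; nucleus convexity index, normalized concavity radius and
#' sphericity index.
#'
#' @param tomo an [RITomogram-class].
#' @param cellMask,nucleusMask [VoxelMask-class]; the nucleus must be a
#'   subset of the cell.
#' @param constants a [morphometryConstants()].
#' @return A one-row data.frame with the nine feature columns in panel
#'   order.
#' @export
featureRecord <- function(tomo, cellMask, nucleusMask,
                          constants = morphometryConstants()) {
  cm <- voxels(cellMask); nm <- voxels(nucleusMask)
  checkSameGrid(cm, nm, "mask grids")
  if (any(nm & !cm)) stop("nucleus mask is not a subset of the cell mask")
  cyto <- VoxelMask(cm & !nm, pitch(cellMask))
  vsC <- volumeAndSurface(cellMask)
  vsN <- volumeAndSurface(nucleusMask)
  data.frame(
    cell_dry_mass_density = dryMassDensity(tomo, cellMask, constants),
    cytoplasm_dry_mass_density = dryMassDensity(tomo, cyto, constants),
    nucleus_dry_mass_density = dryMassDensity(tomo, nucleusMask, constants),
    nucleus_cell_volume_ratio = vsN$volume / vsC$volume,
    nucleus_cell_surface_ratio = vsN$surface / vsC$surface,
    normalized_nucleus_cell_distance = normalizedCentroidDistance(cellMask, nucleusMask),
    nucleus_convexity_index = convexityIndex(nucleusMask),
    normalized_concavity_radius = normalizedConcavityRadius(nucleusMask),
    nucleus_sphericity_index = sphericityIndex(nucleusMask)
  )
}
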