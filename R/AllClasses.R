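#' 3D refractive-index tomogram
#'
#' Container for a single-cell 3D refractive-index (RI) reconstruction on a
#' regular voxel grid. Axes are ordered (x, y, z) in the flow-cytometry frame:
#' cells flow along y, rotate about x, and z is the optical axis. The physical
#' position of voxel `[i, j, k]` (1-based) is
#' `((i - 0.5) * pitch[1], (j - 0.5) * pitch[2], (k - 0.5) * pitch[3])` in
#' micrometres.
#'
#' @slot voxels numeric 3D array of refractive-index values (dimensionless).
#' @slot pitch numeric(3), physical voxel edge length per axis in micrometres.
#' @slot mediumRI refractive index of the surrounding medium (water: 1.334).
#'
#' @seealso [RITomogram()] for construction, [loadVolume()], [writeVolume()]
#' @export
setClass("RITomogram",
  representation(voxels = "array", pitch = "numeric", mediumRI = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3D array")
    if (!all(is.finite(object@voxels)))
      msg <- c(msg, "all voxel values must be finite")
    if (length(object@pitch) != 3L || any(!is.finite(object@pitch)) ||
        any(object@pitch <= 0))
      msg <- c(msg, "pitch must be 3 strictly positive values (um)")
    if (length(object@mediumRI) != 1L || !is.finite(object@mediumRI))
      msg <- c(msg, "mediumRI must be a single finite value")
    if (length(msg)) msg else TRUE
  }
)

#' Binary voxel mask
#'
#' A 3D boolean grid on the same lattice as the tomogram it annotates (cell
#' shell, nucleus ground truth, nucleus prediction, ...).
#'
#' @slot voxels logical 3D array.
#' @slot pitch numeric(3), micrometres per axis, copied from the parent
#'   tomogram.
#'
#' @seealso [VoxelMask()], [loadMask()], [writeMask()]
#' @export
setClass("VoxelMask",
  representation(voxels = "array", pitch = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L || !is.logical(object@voxels))
      msg <- c(msg, "voxels must be a logical 3D array")
    if (length(object@pitch) != 3L || any(!is.finite(object@pitch)) ||
        any(object@pitch <= 0))
      msg <- c(msg, "pitch must be 3 strictly positive values (um)")
    if (length(msg)) msg else TRUE
  }
)

#' Set of cubic voxel blocks (sub-cubes)
#'
#' The intermediate representation of the CSSI segmentation: cubic blocks of
#' voxels, clipped to the cell mask, selected and filtered by the statistical
#' clustering stages. `provenance` records the producing stage
#' (`"partition"`, `"intermediate"`, `"filtered"` or `"downsampled"`).
#'
#' @slot centers integer matrix (n x 3) of 1-based voxel indices of cube
#'   centres.
#' @slot voxelIndices list of integer vectors; 1-based linear indices of the
#'   member voxels of each cube (clipped to the cell mask).
#' @slot side odd integer, cube edge length in voxels.
#' @slot stride integer, lattice step in voxels used by the partition.
#' @slot gridDim integer(3), dimensions of the parent grid.
#' @slot pitch numeric(3), micrometres per axis.
#' @slot provenance character tag of the producing stage.
#'
#' @export
setClass("SubCubeSet",
  representation(centers = "matrix", voxelIndices = "list", side = "integer",
                 stride = "integer", gridDim = "integer", pitch = "numeric",
                 provenance = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@centers) != length(object@voxelIndices))
      msg <- c(msg, "centers and voxelIndices must have matching length")
    if (length(object@side) != 1L || object@side < 3L ||
        object@side %% 2L == 0L)
      msg <- c(msg, "side must be a single odd integer >= 3")
    if (any(lengths(object@voxelIndices) == 0L))
      msg <- c(msg, "every sub-cube must contain at least one voxel")
    if (length(msg)) msg else TRUE
  }
)

#' Numerical cell phantom bundle
#'
#' The output of [generatePhantom()]: a synthetic tomogram plus its
#' ground-truth compartment masks and the measured sphericity of the (possibly
#' indented) nucleus.
#'
#' @slot tomogram [RITomogram-class] with medium + cytoplasm + nucleus RI.
#' @slot cellMask,nucleusMask [VoxelMask-class] ground truth.
#' @slot nucleolusMask [VoxelMask-class] or `NULL`.
#' @slot achievedSphericity mesh-measured sphericity of `nucleusMask`.
#' @slot spec the [phantomSpec()] list used to build the phantom.
#'
#' @export
setClass("PhantomBundle",
  representation(tomogram = "RITomogram", cellMask = "VoxelMask",
                 nucleusMask = "VoxelMask", nucleolusMask = "ANY",
                 achievedSphericity = "numeric", spec = "list")
)

#' Fourier-support occupancy grid
#'
#' Boolean occupancy of spatial frequencies (1/um) covered by a tomographic
#' acquisition geometry, on a centred cubic lattice of step `gridStep`.
#'
#' @slot occupancy logical 3D array (axes kx, ky, kz); the centre voxel is the
#'   zero frequency.
#' @slot gridStep frequency step in 1/um.
#' @slot mode `"rotation"` or `"illumination_scan"`.
#'
#' @export
setClass("OTFSupport",
  representation(occupancy = "array", gridStep = "numeric", mode = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@occupancy)) != 3L || !is.logical(object@occupancy))
      msg <- c(msg, "occupancy must be a logical 3D array")
    if (any(dim(object@occupancy) %% 2L == 0L))
      msg <- c(msg, "occupancy grid must have odd dimensions (centred origin)")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an RITomogram
#'
#' @param voxels numeric 3D array of RI values, axes (x, y, z).
#' @param pitch voxel pitch in micrometres; scalar (isotropic) or length 3.
#' @param mediumRI refractive index of the immersion medium. Default 1.334
#'   (water).
#'
#' @details Values outside the plausible biological range \[1.30, 1.45\]
#' trigger a warning, not an error.
#' @return An [RITomogram-class] object.
#' @examples
#' tomo <- RITomogram(array(1.334, c(8, 8, 8)), pitch = 0.15)
#' dim(tomo)
#' @export
RITomogram <- function(voxels, pitch, mediumRI = 1.334) {
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  storage.mode(voxels) <- "double"
  obj <- new("RITomogram", voxels = voxels, pitch = as.numeric(pitch),
             mediumRI = as.numeric(mediumRI))
  rng <- range(voxels)
  if (rng[1] < 1.30 || rng[2] > 1.45)
    warning(sprintf(
      "RI values [%.4f, %.4f] fall outside the usual biological range [1.30, 1.45]",
      rng[1], rng[2]))
  obj
}

#' Construct a VoxelMask
#'
#' @param voxels logical 3D array (numeric input is thresholded at > 0).
#' @param pitch voxel pitch in micrometres; scalar or length 3.
#' @return A [VoxelMask-class] object.
#' @examples
#' m <- VoxelMask(array(FALSE, c(4, 4, 4)), pitch = 0.15)
#' maskVolume(m)
#' @export
VoxelMask <- function(voxels, pitch) {
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  if (!is.logical(voxels)) {
    dm <- dim(voxels)
    voxels <- array(as.vector(voxels) > 0, dm)
  }
  new("VoxelMask", voxels = voxels, pitch = as.numeric(pitch))
}
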