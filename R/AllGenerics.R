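#' Accessors for voxel containers
#'
#' `voxels()` returns the raw 3D array, `pitch()` the per-axis voxel pitch in
#' micrometres, `mediumRI()` the immersion-medium refractive index and
#' `maskVolume()` the physical volume (um^3) of a mask.
#'
#' @param x an [RITomogram-class], [VoxelMask-class] or [SubCubeSet-class]
#'   object.
#' @return `voxels()` an array; `pitch()` numeric(3); `mediumRI()` and
#'   `maskVolume()` single numerics.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("pitch", function(x) standardGeneric("pitch"))

#' @rdname accessors
#' @export
setGeneric("mediumRI", function(x) standardGeneric("mediumRI"))

#' @rdname accessors
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))

#' @rdname accessors
#' @export
setMethod("voxels", "RITomogram", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("voxels", "VoxelMask", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("pitch", "RITomogram", function(x) x@pitch)

#' @rdname accessors
#' @export
setMethod("pitch", "VoxelMask", function(x) x@pitch)

#' @rdname accessors
#' @export
setMethod("pitch", "SubCubeSet", function(x) x@pitch)

#' @rdname accessors
#' @export
setMethod("mediumRI", "RITomogram", function(x) x@mediumRI)

#' @rdname accessors
#' @export
setMethod("maskVolume", "VoxelMask",
          function(x) sum(x@voxels) * prod(x@pitch))

#' @describeIn RITomogram-class grid dimensions
#' @param x an object
#' @export
setMethod("dim", "RITomogram", function(x) dim(x@voxels))

#' @describeIn VoxelMask-class grid dimensions
#' @param x an object
#' @export
setMethod("dim", "VoxelMask", function(x) dim(x@voxels))

#' @describeIn SubCubeSet-class number of sub-cubes
#' @param x an object
#' @export
setMethod("length", "SubCubeSet", function(x) nrow(x@centers))

setMethod("show", "RITomogram", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("RITomogram %d x %d x %d voxels, pitch (%.4g, %.4g, %.4g) um\n",
              d[1], d[2], d[3], object@pitch[1], object@pitch[2], object@pitch[3]))
  cat(sprintf("  RI range [%.4f, %.4f], medium RI %.4f\n",
              min(object@voxels), max(object@voxels), object@mediumRI))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("VoxelMask %d x %d x %d voxels, %d set (%.2f um^3)\n",
              d[1], d[2], d[3], sum(object@voxels), maskVolume(object)))
})

setMethod("show", "SubCubeSet", function(object) {
  cat(sprintf("SubCubeSet of %d cubes (side %d, stride %d) [%s]\n",
              length(object), object@side, object@stride, object@provenance))
})

setMethod("show", "PhantomBundle", function(object) {
  cat("PhantomBundle\n")
  cat(sprintf("  nucleus sphericity (measured): %.4f\n", object@achievedSphericity))
  show(object@tomogram)
})

setMethod("show", "OTFSupport", function(object) {
  d <- dim(object@occupancy)
  cat(sprintf("OTFSupport [%s] %d x %d x %d, step %.3g 1/um, %d occupied\n",
              object@mode, d[1], d[2], d[3], object@gridStep,
              sum(object@occupancy)))
})
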