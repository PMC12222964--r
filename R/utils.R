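# internal helpers shared across modules

# largest connected component of a logical array; ties broken by smallest
# minimal linear index (deterministic)
largestComponent <- function(vox, connectivity = 26L) {
  dm <- dim(vox)
  lab <- cpp_label3d(as.vector(vox), as.integer(dm), as.integer(connectivity))
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0L) return(array(FALSE, dm))
  sizes <- tabulate(lab, nbins = ncomp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(b) which.max(lab == b), integer(1))
    best <- best[which.min(firsts)]
  }
  array(lab == best, dm)
}

fillHoles <- function(vox) {
  dm <- dim(vox)
  array(cpp_fill_holes(as.vector(vox), as.integer(dm)), dm)
}

# physical centroid (um) of a logical array, voxel-count weighted
maskCentroid <- function(vox, pitch) {
  idx <- which(vox, arr.ind = TRUE)
  (colMeans(idx) - 0.5) * pitch
}

# voxel index triples (1-based) -> physical coordinates of centres (um)
indexToPhysical <- function(ind, pitch) {
  sweep(ind - 0.5, 2L, pitch, `*`)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed below 2^31 from a base seed and stream index
childSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}

stopWithStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

checkSameGrid <- function(a, b, what = "grids") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s differ: %s vs %s", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
  invisible(TRUE)
}
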