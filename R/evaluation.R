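# Segmentation scoring, population discrimination statistics, the seeded
# region-growing baseline and the sphericity-recovery experiment.

#' Voxelwise F1 score of a segmentation
#'
#' Precision, recall and F1 = 2TP / (2TP + FP + FN) of a predicted mask
#' against a ground-truth mask, optionally restricted to an axis-aligned
#' volume of interest (localized F1).
#'
#' @param pred,truth [VoxelMask-class] objects on the same grid.
#' @param voi optional 2 x 3 integer matrix `rbind(lo, hi)` of 0-based,
#'   half-open voxel bounds (as returned by [concavityVOI()]).
#' @return A list with `TP`, `FP`, `FN`, `precision`, `recall`, `f1` and
#'   `voi`.
#' @examples
#' a <- VoxelMask(array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)), 1)
#' f1Score(a, a)$f1
#' @export
f1Score <- function(pred, truth, voi = NULL) {
  pv <- voxels(pred); tv <- voxels(truth)
  checkSameGrid(pv, tv, "mask grids")
  if (!is.null(voi)) {
    stopifnot(is.matrix(voi), nrow(voi) == 2L, ncol(voi) == 3L)
    ix <- (voi[1, 1] + 1L):voi[2, 1]
    iy <- (voi[1, 2] + 1L):voi[2, 2]
    iz <- (voi[1, 3] + 1L):voi[2, 3]
    pv <- pv[ix, iy, iz, drop = FALSE]
    tv <- tv[ix, iy, iz, drop = FALSE]
  }
  TP <- sum(pv & tv); FP <- sum(pv & !tv); FN <- sum(!pv & tv)
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  rec <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else 0
  list(TP = TP, FP = FP, FN = FN, precision = prec, recall = rec, f1 = f1,
       voi = voi)
}

#' Volume of interest around the concave region of a phantom
#'
#' Bounding box (padded by 2 voxels) of the set difference between the
#' voxelized convex hull of the ground-truth nucleus and the nucleus itself,
#' i.e. the carved cup region, for localized F1 scoring.
#'
#' @param bundle a [PhantomBundle-class] with a nonzero indenter depth.
#' @return A 2 x 3 integer matrix `rbind(lo, hi)`, 0-based half-open bounds.
#' @export
concavityVOI <- function(bundle) {
  nm <- voxels(bundle@nucleusMask)
  dm <- dim(nm)
  shell <- array(cpp_shell6(as.vector(nm), as.integer(dm)), dm)
  pts <- (which(shell, arr.ind = TRUE) - 1L) * 1.0
  hull <- array(cpp_voxel_hull(pts, as.integer(dm)), dm)
  gap <- hull & !nm
  if (sum(gap) < 8L) stop("no concavity: the truth nucleus is convex")
  ind <- which(gap, arr.ind = TRUE)
  lo <- pmax(apply(ind, 2, min) - 1L - 2L, 0L)
  hi <- pmin(apply(ind, 2, max) + 2L, dm)
  out <- rbind(lo = as.integer(lo), hi = as.integer(hi))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Rank features by Fisher's discriminant ratio
#'
#' For every shared feature column: FDR = (mu2 - mu3)^2 / (s2^2 + s3^2)
#' between the two populations, plus a two-sided two-sample t-test p-value
#' (Welch by default). Features are returned sorted by decreasing FDR.
#'
#' @param featuresA,featuresB data.frames of per-cell feature records (>= 3
#'   rows each).
#' @param tTestVariant `"welch"` (unequal variances, default) or
#'   `"student"` (pooled variance).
#' @return A data.frame with columns `feature`, `mu2`, `sigma2`, `mu3`,
#'   `sigma3`, `fdr`, `p_value`, sorted by descending FDR. Features with
#'   zero variance in both populations get `NA` with a warning.
#' @examples
#' a <- data.frame(f = rnorm(10, 0), g = 1:10)
#' b <- data.frame(f = rnorm(10, 2), g = 1:10)
#' fdrRank(a, b)
#' @export
fdrRank <- function(featuresA, featuresB, tTestVariant = c("welch", "student")) {
  tTestVariant <- match.arg(tTestVariant)
  if (NROW(featuresA) < 3L || NROW(featuresB) < 3L)
    stop("need at least 3 cells per population")
  shared <- intersect(names(featuresA), names(featuresB))
  shared <- shared[vapply(featuresA[shared], is.numeric, logical(1))]
  rows <- lapply(shared, function(f) {
    x <- featuresA[[f]]; y <- featuresB[[f]]
    mu2 <- mean(x); mu3 <- mean(y)
    s2 <- sd(x); s3 <- sd(y)
    if (s2 == 0 && s3 == 0) {
      warning(sprintf("feature '%s' has zero variance in both populations; FDR undefined", f))
      fdr <- NA_real_; p <- NA_real_
    } else {
      fdr <- (mu2 - mu3)^2 / (s2^2 + s3^2)
      p <- t.test(x, y, var.equal = (tTestVariant == "student"))$p.value
    }
    data.frame(feature = f, mu2 = mu2, sigma2 = s2, mu3 = mu3, sigma3 = s3,
               fdr = fdr, p_value = p)
  })
  out <- do.call(rbind, rows)
  out[order(-out$fdr, out$feature, na.last = TRUE), , drop = FALSE]
}

#' Seeded region-growing baseline
#'
#' Classic 3D seeded region growing: the seed is the guess voxel whose RI is
#' closest to the median RI of the nucleus initial guess; 26-connected
#' neighbours join while their RI stays within `tolerance` of the running
#' region mean; growth is restricted to the cell mask.
#'
#' @param tomo an [RITomogram-class].
#' @param cellMask the cell shell.
#' @param guess the nucleus initial guess ([nucleusInitialGuess()]).
#' @param tolerance RI units; acceptance half-width around the running mean.
#' @return A [VoxelMask-class].
#' @export
regionGrowing <- function(tomo, cellMask, guess, tolerance = 0.01) {
  g <- voxels(guess)
  if (!any(g)) stop("empty guess")
  vox <- voxels(tomo)
  gidx <- which(g)
  medRI <- median(vox[gidx])
  seed <- gidx[which.min(abs(vox[gidx] - medRI))]
  out <- cpp_region_grow(as.vector(vox), as.integer(dim(vox)),
                         as.vector(voxels(cellMask)), seed - 1L, tolerance)
  if (!any(out)) stop("region growing produced an empty mask")
  VoxelMask(array(out, dim(vox)), pitch(tomo))
}

#' Sphericity-recovery experiment
#'
#' For each simulated nucleus sphericity level (and repeat), generates a cup
#' phantom, segments it with the requested algorithms and scores voxelwise
#' F1, localized F1 (inside the concavity VOI, levels < 1 only) and the
#' sphericity estimated from each predicted mask. Fully seeded and
#' reproducible.
#'
#' @param levels simulated sphericity targets in (0, 1].
#' @param algorithms subset of `c("concave", "convex", "rg")`.
#' @param nRepeats phantoms per level.
#' @param seed master seed; every phantom derives its own stream from it.
#' @param spec base [phantomSpec()] (the target sphericity and seed of each
#'   run are overridden).
#' @param cssiCfg,closingCfg,rgTolerance algorithm settings.
#' @return A data.frame with one row per (level, repeat, algorithm):
#'   `level`, `repeat_`, `algorithm`, `truth_sphericity`, `f1`, `f1_local`,
#'   `est_sphericity`.
#' @export
recoveryExperiment <- function(levels = c(0.75, 0.80, 0.85, 0.90, 0.95, 1.00),
                               algorithms = c("concave", "convex", "rg"),
                               nRepeats = 1L, seed = 1L,
                               spec = phantomSpec(),
                               cssiCfg = cssiConfig(),
                               closingCfg = NULL, rgTolerance = 0.01) {
  stopifnot(all(levels > 0), all(levels <= 1))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  rows <- list()
  run <- 0L
  for (li in seq_along(levels)) {
    for (rep_ in seq_len(nRepeats)) {
      run <- run + 1L
      sp <- spec
      sp$targetSphericity <- levels[li]
      sp$seed <- childSeed(seed, run)
      bundle <- generatePhantom(sp)
      voi <- if (levels[li] < 1 && bundle@spec$indenterDepth > 0)
        tryCatch(concavityVOI(bundle), error = function(e) NULL) else NULL
      segCfg <- cssiCfg
      segCfg$seed <- childSeed(seed, run + 10000L)
      for (alg in algorithms) {
        predMask <- tryCatch(switch(alg,
          concave = segmentNucleus(bundle@tomogram, "concave", segCfg, closingCfg),
          convex = segmentNucleus(bundle@tomogram, "convex", segCfg, closingCfg),
          rg = {
            cellMask <- makeCellMask(bundle@tomogram)
            guess <- nucleusInitialGuess(bundle@tomogram, cellMask,
                                         segCfg$guessPercentile)
            regionGrowing(bundle@tomogram, cellMask, guess, rgTolerance)
          }), error = function(e) {
            warning(sprintf("level %.2f repeat %d %s failed: %s",
                            levels[li], rep_, alg, conditionMessage(e)))
            NULL
          })
        if (is.null(predMask)) next
        sc <- f1Score(predMask, bundle@nucleusMask)
        scLocal <- if (!is.null(voi)) f1Score(predMask, bundle@nucleusMask, voi) else NULL
        rows[[length(rows) + 1L]] <- data.frame(
          level = levels[li], repeat_ = rep_, algorithm = alg,
          truth_sphericity = bundle@achievedSphericity,
          f1 = sc$f1,
          f1_local = if (is.null(scLocal)) NA_real_ else scLocal$f1,
          est_sphericity = sphericityIndex(predMask))
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate two phantom cohorts and extract their feature tables
#'
#' Generates `nPerGroup` phantoms per population with biological jitter on
#' the geometry, differing in mean nucleus sphericity and nucleus RI, and
#' computes the nine-feature record of every cell. Features may be measured
#' on ground-truth masks (`masks = "truth"`, isolating feature statistics
#' from segmentation noise) or on concave-CSSI segmentations
#' (`masks = "concave"`).
#'
#' @param nPerGroup cells per population.
#' @param sphericityA,sphericityB mean simulated nucleus sphericity of each
#'   population.
#' @param sphericitySD population spread of the sphericity target.
#' @param nucleusRIShift added to the nucleus mean RI of population B.
#' @param seed master seed.
#' @param spec base [phantomSpec()].
#' @param masks `"truth"` or `"concave"`.
#' @return A list with data.frames `A` and `B`.
#' @export
simulateCohorts <- function(nPerGroup = 63L, sphericityA = 0.95,
                            sphericityB = 0.80, sphericitySD = 0.02,
                            nucleusRIShift = 0.008, seed = 1L,
                            spec = phantomSpec(gridShape = 64, pitch = 0.18,
                                               cellRadius = 4.4,
                                               nucleusRadius = 2.6,
                                               indenterRadius = 2.0),
                            masks = c("truth", "concave")) {
  masks <- match.arg(masks)
  makeGroup <- function(meanSph, riShift, offsetStream) {
    rows <- vector("list", nPerGroup)
    for (i in seq_len(nPerGroup)) {
      st <- childSeed(seed, offsetStream + i)
      pars <- withSeed(st, list(
        sph = min(1, max(0.7, rnorm(1, meanSph, sphericitySD))),
        cellJitter = runif(1, 0.92, 1.08),
        nucJitter = runif(1, 0.92, 1.08),
        off = runif(3, -0.4, 0.4)))
      sp <- spec
      sp$cellRadius <- spec$cellRadius * pars$cellJitter
      sp$nucleusRadius <- spec$nucleusRadius * pars$nucJitter
      sp$nucleusOffset <- pars$off
      sp$riNucleus <- spec$riNucleus + riShift
      sp$targetSphericity <- pars$sph
      sp$seed <- childSeed(st, 7L)
      bundle <- generatePhantom(sp)
      nuc <- if (masks == "truth") bundle@nucleusMask
      else segmentNucleus(bundle@tomogram,
                          cssiCfg = cssiConfig(seed = childSeed(st, 11L)))
      cell <- if (masks == "truth") bundle@cellMask
      else makeCellMask(bundle@tomogram)
      nucIn <- VoxelMask(voxels(nuc) & voxels(cell), pitch(cell))
      rows[[i]] <- featureRecord(bundle@tomogram, cell, nucIn)
    }
    do.call(rbind, rows)
  }
  list(A = makeGroup(sphericityA, 0, 0L),
       B = makeGroup(sphericityB, nucleusRIShift, 100000L))
}
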