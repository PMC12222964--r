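# Fourier-coverage (OTF support) analysis of tomographic acquisition
# geometries: sample rotation about the x-axis (flow tomography) versus
# illumination scanning in the y-z plane (static tomography with its missing
# cone).

#' OTF configuration
#'
#' @param na detection numerical aperture (must be below `n0`).
#' @param wavelength illumination wavelength in um.
#' @param n0 medium refractive index.
#' @param mode `"rotation"` (sample rotation about x) or
#'   `"illumination_scan"` (beam tilt in the y-z plane).
#' @param angularStep degrees; angular sampling of the illumination arc.
#' @param gridStep frequency grid step in 1/um.
#' @return A validated list of class `otfConfig`. Derived quantities:
#'   `k0 = n0 / wavelength` (Ewald radius), `a = na / wavelength` (lateral
#'   cutoff) and `c = sqrt(k0^2 - a^2)`.
#' @export
otfConfig <- function(na = 1.3, wavelength = 0.532, n0 = 1.334,
                      mode = c("rotation", "illumination_scan"),
                      angularStep = 0.5, gridStep = 0.02) {
  mode <- match.arg(mode)
  stopifnot(na > 0, wavelength > 0, gridStep > 0, angularStep > 0)
  if (na >= n0) stop("numerical aperture must be below the medium RI")
  cfg <- list(na = na, wavelength = wavelength, n0 = n0, mode = mode,
              angularStep = angularStep, gridStep = gridStep,
              k0 = n0 / wavelength, a = na / wavelength)
  cfg$c <- sqrt(cfg$k0^2 - cfg$a^2)
  class(cfg) <- "otfConfig"
  cfg
}

#' Axial extent of a single Ewald cap
#'
#' The axial (kz) depth of the diffraction cap of one coherent projection,
#' `k0 - c = (n0 - sqrt(n0^2 - NA^2)) / wavelength`: the axial cutoff of a
#' non-scanned transmission geometry and the source of the missing-cone
#' anisotropy of static tomography.
#'
#' @param cfg an [otfConfig()].
#' @return Frequency in 1/um.
#' @examples
#' capAxialExtent(otfConfig()) # ~1.945 for NA 1.3, 532 nm, water
#' @export
capAxialExtent <- function(cfg = otfConfig()) {
  (cfg$n0 - sqrt(cfg$n0^2 - cfg$na^2)) / cfg$wavelength
}

#' Analytic per-axis cutoff frequencies
#'
#' Closed-form maximum occupied |frequency| along each axis of the swept-cap
#' support. Rotation about x: `cutoff_x = NA / wavelength` and
#' `cutoff_y = cutoff_z = sqrt(a^2 + (k0 - c)^2)` (the cap rim swept
#' on-axis). Illumination scan: `(a, 2a, k0 - c)`.
#'
#' @param cfg an [otfConfig()].
#' @return Named numeric: `cutoff_x`, `cutoff_y`, `cutoff_z`,
#'   `resolution_ratio`.
#' @export
otfCutoffs <- function(cfg = otfConfig()) {
  ext <- capAxialExtent(cfg)
  cut <- if (cfg$mode == "rotation") {
    rim <- sqrt(cfg$a^2 + ext^2)
    c(cutoff_x = cfg$a, cutoff_y = rim, cutoff_z = rim)
  } else {
    c(cutoff_x = cfg$a, cutoff_y = 2 * cfg$a, cutoff_z = ext)
  }
  c(cut, resolution_ratio = unname(min(cut) / max(cut)))
}

#' Build the voxelized OTF support
#'
#' Occupancy is evaluated per frequency voxel centre against the solid swept
#' by the Ewald caps of the configuration: for sample rotation, the annulus
#' swept by the cap through 360 degrees about kx (evaluated in closed form);
#' for illumination scanning, the kz interval covered by the caps shifted by
#' each incident wavevector of the arc (sampled at `angularStep`), then
#' symmetrized under k -> -k.
#'
#' @param cfg an [otfConfig()].
#' @return An [OTFSupport-class].
#' @export
buildSupport <- function(cfg = otfConfig()) {
  h <- cfg$gridStep
  cut <- otfCutoffs(cfg)
  half <- ceiling((cut[1:3] + 2 * h) / h)
  dims <- as.integer(2L * half + 1L)
  occ <- if (cfg$mode == "rotation") {
    cpp_otf_rotation(dims, rep(h, 3), cfg$k0, cfg$a)
  } else {
    nTheta <- max(31L, 2L * as.integer(ceiling(
      asin(cfg$a / cfg$k0) * 180 / pi / cfg$angularStep)) + 1L)
    cpp_otf_scan(dims, rep(h, 3), cfg$k0, cfg$a, nTheta)
  }
  new("OTFSupport", occupancy = array(occ, dims), gridStep = h,
      mode = cfg$mode)
}

#' Metrics of a voxelized OTF support
#'
#' Per-axis maximum occupied |frequency| (over the full support, not only
#' on-axis), the min/max resolution ratio, and the support volume (occupied
#' voxels times `gridStep^3`).
#'
#' @param support an [OTFSupport-class].
#' @return A list with `cutoff_x`, `cutoff_y`, `cutoff_z`,
#'   `resolution_ratio`, `volume`.
#' @export
supportMetrics <- function(support) {
  occ <- support@occupancy
  if (!any(occ)) stop("empty OTF support")
  h <- support@gridStep
  dm <- dim(occ)
  ctr <- (dm + 1L) %/% 2L
  ind <- which(occ, arr.ind = TRUE)
  cut <- vapply(1:3, function(a) max(abs(ind[, a] - ctr[a])) * h, numeric(1))
  names(cut) <- c("cutoff_x", "cutoff_y", "cutoff_z")
  list(cutoff_x = cut[[1]], cutoff_y = cut[[2]], cutoff_z = cut[[3]],
       resolution_ratio = min(cut) / max(cut),
       volume = sum(occ) * h^3)
}

#' One-call OTF comparison of both geometries
#'
#' Builds both supports at the same grid step and reports cutoffs,
#' resolution ratios, volumes and the percent volume advantage of the
#' rotation geometry over the illumination scan.
#'
#' @param cfg base [otfConfig()] (the `mode` field is overridden).
#' @return A list with `rotation`, `scan` (each a [supportMetrics()] list)
#'   and `percent_volume_advantage`.
#' @export
otfCompare <- function(cfg = otfConfig()) {
  rotCfg <- cfg; rotCfg$mode <- "rotation"
  scanCfg <- cfg; scanCfg$mode <- "illumination_scan"
  rot <- supportMetrics(buildSupport(rotCfg))
  scan <- supportMetrics(buildSupport(scanCfg))
  list(rotation = rot, scan = scan,
       percent_volume_advantage = 100 * (rot$volume - scan$volume) / scan$volume)
}
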