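# Volume, mask and feature-table I/O.
#
# Grid convention (global): voxel index (i, j, k) is 1-based in R; the
# physical position of a voxel centre is ((i - 0.5) * pitch_x, ...) um.
# TIFF pages map to z; within a page, rows map to y and columns to x.
# Volumes are stored as float32 (TIFF normalized with a scale/offset sidecar,
# NRRD raw little-endian); masks as 8-bit 0/255.

nrrdTypeInfo <- list(
  "float"         = list(size = 4L, what = "double", r = "double"),
  "double"        = list(size = 8L, what = "double", r = "double"),
  "unsigned char" = list(size = 1L, what = "integer", r = "integer"),
  "uchar"         = list(size = 1L, what = "integer", r = "integer")
)

readNRRD <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop(sprintf("'%s' is not an NRRD file", path))
  fields <- list(); keys <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop(sprintf("'%s': truncated NRRD header", path))
    if (line == "") break
    if (grepl("^#", line)) next
    if (grepl(":=", line, fixed = TRUE)) {
      kv <- strsplit(line, ":=", fixed = TRUE)[[1]]
      keys[[trimws(kv[1])]] <- trimws(kv[2])
    } else {
      kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
      fields[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- fields$type
  ti <- nrrdTypeInfo[[type]]
  if (is.null(ti)) stop(sprintf("'%s': unsupported NRRD type '%s'", path, type))
  n <- prod(sizes)
  enc <- if (is.null(fields$encoding)) "raw" else fields$encoding
  if (enc == "raw") {
    dat <- readBin(con, ti$what, n = n, size = ti$size,
                   signed = ti$size > 2L,
                   endian = if (identical(fields$endian, "big")) "big" else "little")
  } else if (enc %in% c("ascii", "txt", "text")) {
    dat <- scan(con, what = double(), n = n, quiet = TRUE)
  } else stop(sprintf("'%s': unsupported NRRD encoding '%s'", path, enc))
  if (length(dat) != n) stop(sprintf("'%s': expected %d values, found %d", path, n, length(dat)))
  spac <- if (!is.null(fields$spacings))
    as.numeric(strsplit(fields$spacings, "\\s+")[[1]]) else NULL
  list(data = dat, sizes = sizes, spacings = spac, type = type, keys = keys)
}

writeNRRD <- function(data, sizes, path, type = "float", spacings = NULL,
                      keys = list(), encoding = "raw") {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %s", paste(sizes, collapse = " ")),
           sprintf("encoding: %s", encoding),
           "endian: little")
  if (!is.null(spacings))
    hdr <- c(hdr, sprintf("spacings: %s", paste(format(spacings, digits = 17), collapse = " ")))
  for (k in names(keys)) hdr <- c(hdr, sprintf("%s:=%s", k, keys[[k]]))
  writeLines(c(hdr, ""), con, sep = "\n")
  ti <- nrrdTypeInfo[[type]]
  if (encoding == "raw") {
    if (ti$what == "integer")
      writeBin(as.integer(data), con, size = ti$size, endian = "little")
    else
      writeBin(as.double(data), con, size = ti$size, endian = "little")
  } else {
    writeLines(paste(format(data, digits = 9), collapse = " "), con)
  }
  invisible(path)
}

sidecarPath <- function(path) paste0(path, ".json")

isTIFF <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)
isNRRD <- function(path) grepl("\\.nrrd$", path, ignore.case = TRUE)

#' Read a 3D refractive-index tomogram
#'
#' Reads a multi-page float TIFF (with its JSON metadata sidecar) or an NRRD
#' volume. TIFF volumes are stored normalized; the sidecar fields `ri_offset`
#' and `ri_scale` restore physical RI values. NRRD files carry pitch in their
#' `spacings` header field.
#'
#' @param path path to a `.tif`/`.tiff` or `.nrrd` volume.
#' @param metadataPath optional JSON sidecar path; defaults to
#'   `paste0(path, ".json")` when present.
#' @return An [RITomogram-class].
#' @seealso [writeVolume()]
#' @export
loadVolume <- function(path, metadataPath = NULL) {
  if (!file.exists(path)) stop(sprintf("volume file '%s' does not exist", path))
  if (is.null(metadataPath) && file.exists(sidecarPath(path)))
    metadataPath <- sidecarPath(path)
  meta <- if (!is.null(metadataPath)) {
    if (!file.exists(metadataPath))
      stop(sprintf("metadata file '%s' does not exist", metadataPath))
    jsonlite::fromJSON(metadataPath)
  } else list()
  if (isNRRD(path)) {
    nr <- readNRRD(path)
    if (length(nr$sizes) != 3L)
      stop(sprintf("'%s': volume must be 3D (got %dD)", path, length(nr$sizes)))
    vox <- array(nr$data, nr$sizes)
    pitchv <- meta$pitch_um
    if (is.null(pitchv)) pitchv <- nr$spacings
    if (is.null(pitchv))
      stop(sprintf("'%s': missing voxel pitch (no NRRD spacings, no sidecar pitch_um)", path))
    medium <- meta$medium_ri
    if (is.null(medium)) medium <- suppressWarnings(as.numeric(nr$keys[["medium_ri"]]))
    if (is.null(medium) || !length(medium) || is.na(medium)) medium <- 1.334
  } else if (isTIFF(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop(sprintf("'%s': volume must be 3D (TIFF has %d page)", path, length(pages)))
    nz <- length(pages)
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    vox <- array(0, c(nx, ny, nz))
    for (k in seq_len(nz)) vox[, , k] <- t(pages[[k]])
    offset <- if (is.null(meta$ri_offset)) 0 else meta$ri_offset
    scalef <- if (is.null(meta$ri_scale)) 1 else meta$ri_scale
    vox <- vox * scalef + offset
    pitchv <- meta$pitch_um
    if (is.null(pitchv))
      stop(sprintf("'%s': missing voxel pitch (no sidecar field pitch_um)", path))
    medium <- if (is.null(meta$medium_ri)) 1.334 else meta$medium_ri
  } else stop(sprintf("'%s': unsupported volume format (use .tif/.tiff or .nrrd)", path))
  RITomogram(vox, pitch = pitchv, mediumRI = medium)
}

#' Write a 3D refractive-index tomogram
#'
#' Writes a float32 volume plus a JSON sidecar (`<path>.json`) holding the
#' voxel pitch, medium RI and a small creation log. NRRD output is lossless
#' at float32 precision; TIFF output is normalized to \[0, 1\] and the affine
#' restore parameters are stored in the sidecar.
#'
#' @param tomo an [RITomogram-class].
#' @param path output path (`.nrrd` or `.tif`/`.tiff`).
#' @param overwrite overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(tomo, path, overwrite = FALSE) {
  stopifnot(is(tomo, "RITomogram"))
  if (file.exists(path) && !overwrite)
    stop(sprintf("'%s' exists; set overwrite = TRUE to replace it", path))
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory '%s' does not exist", dirname(path)))
  dm <- dim(tomo)
  meta <- list(pitch_um = pitch(tomo), medium_ri = mediumRI(tomo),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               creator = sprintf("cssi3d %s", as.character(utils::packageVersion("cssi3d"))))
  if (isNRRD(path)) {
    writeNRRD(as.vector(voxels(tomo)), dm, path, type = "float",
              spacings = pitch(tomo),
              keys = list(medium_ri = format(mediumRI(tomo), digits = 10)))
  } else if (isTIFF(path)) {
    # normalize into [0, 1] for the TIFF container
    offset <- 1.25; scalef <- 0.25
    meta$ri_offset <- offset; meta$ri_scale <- scalef
    norm <- (voxels(tomo) - offset) / scalef
    if (min(norm) < 0 || max(norm) > 1)
      stop("RI values outside the TIFF storage range [1.25, 1.50]; use NRRD output")
    pages <- lapply(seq_len(dm[3]), function(k) t(norm[, , k]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else stop(sprintf("'%s': unsupported volume format (use .tif/.tiff or .nrrd)", path))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             sidecarPath(path))
  invisible(path)
}

#' Read / write binary masks
#'
#' Masks are stored as 8-bit 0/255 TIFF or NRRD volumes and thresholded at
#' `> 0` on read.
#'
#' @param path mask file (`.tif`/`.tiff` or `.nrrd`).
#' @param pitch voxel pitch in um, used when the container lacks one.
#' @param reference optional [RITomogram-class] or [VoxelMask-class]; when
#'   given, the mask grid must match its grid (error otherwise) and its pitch
#'   is inherited.
#' @return [loadMask()] a [VoxelMask-class]; [writeMask()] the path,
#'   invisibly.
#' @export
loadMask <- function(path, pitch = NULL, reference = NULL) {
  if (!file.exists(path)) stop(sprintf("mask file '%s' does not exist", path))
  if (isNRRD(path)) {
    nr <- readNRRD(path)
    if (length(nr$sizes) != 3L) stop(sprintf("'%s': mask must be 3D", path))
    vox <- array(nr$data > 0, nr$sizes)
    if (is.null(pitch)) pitch <- nr$spacings
  } else if (isTIFF(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L) stop(sprintf("'%s': mask must be 3D", path))
    nz <- length(pages); ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    vox <- array(FALSE, c(nx, ny, nz))
    for (k in seq_len(nz)) vox[, , k] <- t(pages[[k]]) > 0
  } else stop(sprintf("'%s': unsupported mask format", path))
  if (!is.null(reference)) {
    if (!identical(dim(vox), dim(reference)))
      stop(sprintf("mask grid %s does not match reference grid %s",
                   paste(dim(vox), collapse = "x"),
                   paste(dim(reference), collapse = "x")))
    pitch <- pitch(reference)
  }
  if (is.null(pitch)) stop(sprintf("'%s': missing pitch (give pitch= or reference=)", path))
  VoxelMask(vox, pitch)
}

#' @rdname loadMask
#' @param mask a [VoxelMask-class].
#' @param overwrite overwrite an existing file? Default `FALSE`.
#' @export
writeMask <- function(mask, path, overwrite = FALSE) {
  stopifnot(is(mask, "VoxelMask"))
  if (file.exists(path) && !overwrite)
    stop(sprintf("'%s' exists; set overwrite = TRUE to replace it", path))
  dm <- dim(mask)
  if (isNRRD(path)) {
    writeNRRD(as.integer(voxels(mask)) * 255L, dm, path, type = "unsigned char",
              spacings = pitch(mask))
  } else if (isTIFF(path)) {
    pages <- lapply(seq_len(dm[3]), function(k) t(voxels(mask)[, , k]) * 1.0)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else stop(sprintf("'%s': unsupported mask format", path))
  invisible(path)
}

featureUnits <- c(
  cell_dry_mass_density      = "pg/um^3",
  cytoplasm_dry_mass_density = "pg/um^3",
  nucleus_dry_mass_density   = "pg/um^3",
  nucleus_cell_volume_ratio  = "1",
  nucleus_cell_surface_ratio = "1",
  normalized_nucleus_cell_distance = "1",
  nucleus_convexity_index    = "1",
  normalized_concavity_radius = "1",
  nucleus_sphericity_index   = "1"
)

#' Write / read a per-cell feature table
#'
#' One row per cell, one column per feature, in the fixed panel order of the
#' nine morphological/biophysical descriptors. A `# units:` comment line
#' records units.
#'
#' @param records a data.frame of feature records ([featureRecord()] rows).
#' @param path output CSV path.
#' @return [writeFeatureTable()] the path invisibly; [readFeatureTable()] a
#'   data.frame.
#' @export
writeFeatureTable <- function(records, path) {
  if (NROW(records) == 0L) stop("empty record list")
  records <- as.data.frame(records)
  want <- names(featureUnits)
  miss <- setdiff(want, names(records))
  if (length(miss))
    stop(sprintf("records lack feature column(s): %s", paste(miss, collapse = ", ")))
  extra <- setdiff(names(records), want)
  records <- records[, c(want, extra), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s",
                     paste(sprintf("%s [%s]", want, featureUnits[want]), collapse = "; ")),
             con)
  utils::write.csv(format(records, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a pipeline configuration file
#'
#' A single YAML file with sections `phantom`, `cssi`, `closing`,
#' `morphometry` and `otf`; every absent entry falls back to the package
#' default of the corresponding constructor.
#'
#' @param path YAML file.
#' @return A named list of configuration objects.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  list(
    phantom = do.call(phantomSpec, cfg$phantom %||% list()),
    cssi = do.call(cssiConfig, cfg$cssi %||% list()),
    closing = do.call(closingConfig, cfg$closing %||% list()),
    morphometry = do.call(morphometryConstants, cfg$morphometry %||% list()),
    otf = do.call(otfConfig, cfg$otf %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
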