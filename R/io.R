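## File formats: images and volumes as multi-page TIFF with a JSON
## sidecar carrying geometry, value scaling and masks; manifests and
## metrics as JSON; FRC curves as CSV. TIFF samples are stored scaled to
## [0, 1] (the range is recorded in the sidecar) and masked values are
## carried as an extra 0/1 mask page per channel.

.sidecar <- function(path) paste0(path, ".json")

## Write named channels (matrices, possibly with NA) as one multi-page
## TIFF + sidecar. `meta` is merged into the sidecar as-is.
.writeChannels <- function(path, channels, meta = list()) {
  pages <- list()
  chan_meta <- list()
  for (nm in names(channels)) {
    m <- channels[[nm]]
    bad <- !is.finite(m)
    fin <- m[!bad]
    vmin <- if (length(fin)) min(fin) else 0
    vmax <- if (length(fin)) max(fin) else 1
    scl <- if (vmax > vmin) (m - vmin) / (vmax - vmin) else m * 0
    scl[bad] <- 0
    pages[[length(pages) + 1L]] <- scl
    chan_meta[[nm]] <- list(vmin = vmin, vmax = vmax, masked = any(bad))
    if (any(bad)) pages[[length(pages) + 1L]] <- (!bad) * 1
  }
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  meta$channels <- chan_meta
  jsonlite::write_json(meta, .sidecar(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.readChannels <- function(path) {
  meta <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- list()
  pg <- 1L
  for (nm in names(meta$channels)) {
    cm <- meta$channels[[nm]]
    m <- pages[[pg]] * (cm$vmax - cm$vmin) + cm$vmin
    pg <- pg + 1L
    if (isTRUE(cm$masked)) {
      mask <- pages[[pg]] < 0.5
      m[mask] <- NA_real_
      pg <- pg + 1L
    }
    out[[nm]] <- m
  }
  attr(out, "meta") <- meta
  out
}

#' Write a beamlet frame to TIFF + JSON sidecar
#'
#' @param frame a [BeamletFrame-class]
#' @param path output TIFF path (a `.json` sidecar is written next to it)
#' @return `path`, invisibly
#' @export
writeFrame <- function(frame, path) {
  stopifnot(is(frame, "BeamletFrame"))
  .writeChannels(path, list(intensity = frame@intensity),
                 meta = list(kind = "BeamletFrame",
                             grid_origin = frame@gridOrigin,
                             grid_pitch = frame@gridPitch,
                             grid_dim = frame@gridDim,
                             modulator_offset_um = frame@modulatorOffset * 1e6))
}

#' Read a beamlet frame written by [writeFrame()]
#' @param path TIFF path
#' @return a [BeamletFrame-class]
#' @export
readFrame <- function(path) {
  ch <- .readChannels(path)
  meta <- attr(ch, "meta")
  new("BeamletFrame", intensity = ch$intensity,
      gridOrigin = as.numeric(meta$grid_origin),
      gridPitch = as.numeric(meta$grid_pitch),
      gridDim = as.integer(meta$grid_dim),
      modulatorOffset = as.numeric(meta$modulator_offset_um) * 1e-6)
}

#' Write a stitched projection (t, alpha_x, alpha_y) to TIFF + sidecar
#' @param proj a [StitchedProjection-class]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
writeStitched <- function(proj, path) {
  stopifnot(is(proj, "StitchedProjection"))
  .writeChannels(path,
                 list(t = proj@t, alpha_x = proj@alphaX,
                      alpha_y = proj@alphaY),
                 meta = list(kind = "StitchedProjection",
                             angle_rad = proj@angle,
                             pitch_um = proj@pitch * 1e6))
}

#' Read a stitched projection written by [writeStitched()]
#' @param path TIFF path
#' @return a [StitchedProjection-class]
#' @export
readStitched <- function(path) {
  ch <- .readChannels(path)
  meta <- attr(ch, "meta")
  new("StitchedProjection", t = ch$t, alphaX = ch$alpha_x,
      alphaY = ch$alpha_y, angle = as.numeric(meta$angle_rad),
      pitch = as.numeric(meta$pitch_um) * 1e-6)
}

#' Write a phase map to TIFF + sidecar
#' @param pm a [PhaseMap-class]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
writePhaseMap <- function(pm, path) {
  stopifnot(is(pm, "PhaseMap"))
  .writeChannels(path, list(dphi = pm@dphi),
                 meta = list(kind = "PhaseMap", angle_rad = pm@angle,
                             pitch_um = pm@pitch * 1e6))
}

#' Read a phase map written by [writePhaseMap()]
#' @param path TIFF path
#' @return a [PhaseMap-class]
#' @export
readPhaseMap <- function(path) {
  ch <- .readChannels(path)
  meta <- attr(ch, "meta")
  new("PhaseMap", dphi = ch$dphi, pitch = as.numeric(meta$pitch_um) * 1e-6,
      angle = as.numeric(meta$angle_rad))
}

#' Write a reconstructed volume as a TIFF stack (one page per slice)
#' @param vol a [Volume-class]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume"))
  d <- dim(vol@voxels)
  vmin <- min(vol@voxels); vmax <- max(vol@voxels)
  rng <- if (vmax > vmin) vmax - vmin else 1
  pages <- lapply(seq_len(d[1L]), function(y)
    (matrix(vol@voxels[y, , ], d[2L], d[3L]) - vmin) / rng)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  jsonlite::write_json(
    list(kind = "Volume", channel = vol@channel,
         voxel_size_um = vol@voxelSize * 1e6, dim = d,
         vmin = vmin, vmax = vmax),
    .sidecar(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a volume written by [writeVolume()]
#' @param path TIFF path
#' @return a [Volume-class]
#' @export
readVolume <- function(path) {
  meta <- jsonlite::read_json(.sidecar(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  vol <- array(0, d)
  for (y in seq_len(d[1L]))
    vol[y, , ] <- pages[[y]] * (meta$vmax - meta$vmin) + meta$vmin
  new("Volume", voxels = vol, voxelSize = as.numeric(meta$voxel_size_um) * 1e-6,
      channel = meta$channel)
}

#' Export an FRC curve as CSV
#'
#' Columns: `freq` (cycles/pixel), `frc`, `threshold`.
#'
#' @param curve an [FRCCurve-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeFRCCurve <- function(curve, path) {
  stopifnot(is(curve, "FRCCurve"))
  utils::write.csv(data.frame(freq = curve@freq, frc = curve@frc,
                              threshold = curve@threshold),
                   path, row.names = FALSE)
  invisible(path)
}
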