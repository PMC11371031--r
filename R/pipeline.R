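## End-to-end pipeline binding the stages together:
## simulate -> track/stitch -> integrate -> reconstruct -> metrics.
## Every stage writes its artifacts plus a done-marker JSON with
## provenance (config hash, seed, package version, timing); a stage whose
## marker exists is skipped, so a partially deleted output directory is
## resumed rather than recomputed.

.cfg_error <- function(msg)
  stop(structure(class = c("beamtrack_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))

.data_error <- function(msg)
  stop(structure(class = c("beamtrack_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.stage_marker <- function(out_dir, stage) {
  file.path(out_dir, sprintf("stage_%s.json", stage))
}

.mark_done <- function(out_dir, stage, config, info = list()) {
  payload <- c(list(stage = stage, config_hash = .config_hash(config),
                    package_version = as.character(
                      utils::packageVersion("BeamTrack")),
                    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               info)
  jsonlite::write_json(payload, .stage_marker(out_dir, stage),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

.geom_from_config <- function(config) {
  g <- config$geometry
  if (is.null(g)) .cfg_error("config is missing the 'geometry' section")
  req <- c("z_od", "mean_energy", "pixel_size", "modulator_period")
  miss <- setdiff(req, names(g))
  if (length(miss))
    .cfg_error(paste("geometry config missing:", paste(miss, collapse = ", ")))
  SetupGeometry(z_od = g$z_od, mean_energy = g$mean_energy,
                pixel_size = g$pixel_size,
                modulator_period = g$modulator_period,
                aperture_diameter = if (is.null(g$aperture_diameter)) 15
                                    else g$aperture_diameter,
                n_subpitch = if (is.null(g$n_subpitch)) 1L else g$n_subpitch)
}

.phantom_from_config <- function(config, geom) {
  p <- config$simulate$phantom
  if (is.null(p)) .cfg_error("config is missing 'simulate$phantom'")
  discs <- do.call(rbind, lapply(p$discs, as.data.frame))
  if (is.null(discs)) .cfg_error("phantom needs at least one disc")
  cylinderPhantom(n = p$n,
                  n_slices = if (is.null(p$n_slices)) 1L else p$n_slices,
                  voxel_size = samplingPitch(geom) * 1e6,
                  discs = discs)
}

.frame_path <- function(dir, ia, ir) {
  file.path(dir, sprintf("sample_a%04d_r%02d.tif", ia, ir))
}

.stage_simulate <- function(config, out_dir) {
  dir <- file.path(out_dir, "frames")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- .geom_from_config(config)
  sim_cfg <- config$simulate
  if (is.null(sim_cfg)) .cfg_error("config is missing the 'simulate' section")
  phantom <- .phantom_from_config(config, geom)
  t0 <- Sys.time()
  scan <- simulateScan(phantom, geom,
                       n_projections = sim_cfg$n_projections,
                       flux = if (is.null(sim_cfg$flux)) 1e4 else sim_cfg$flux,
                       seed = if (is.null(sim_cfg$seed)) 1L else sim_cfg$seed,
                       sigma_px = if (is.null(sim_cfg$sigma_px)) 2
                                  else sim_cfg$sigma_px)
  for (r in seq_along(scan$flats))
    writeFrame(scan$flats[[r]], file.path(dir, sprintf("flat_r%02d.tif", r)))
  .writeChannels(file.path(dir, "dark.tif"), list(intensity = scan$dark),
                 meta = list(kind = "DarkFrame"))
  for (ia in seq_along(scan$sample))
    for (r in seq_along(scan$sample[[ia]]))
      writeFrame(scan$sample[[ia]][[r]], .frame_path(dir, ia, r))
  for (ia in seq_along(scan$truth))
    .writeChannels(file.path(dir, sprintf("truth_a%04d.tif", ia)),
                   list(t = scan$truth[[ia]]$t, dphi = scan$truth[[ia]]$dphi),
                   meta = list(kind = "GroundTruth", angle_rad = scan$angles[ia]))
  manifest <- list(angles_rad = scan$angles,
                   n_raster = length(scan$flats),
                   offsets_um = scan$offsets * 1e6,
                   n_angles = length(scan$angles),
                   seed = sim_cfg$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_stage("simulate", "%d angles x %d raster positions in %.1f s",
             manifest$n_angles, manifest$n_raster,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  .mark_done(out_dir, "simulate", config,
             list(n_angles = manifest$n_angles,
                  n_raster = manifest$n_raster))
}

.stage_track <- function(config, out_dir) {
  fdir <- file.path(out_dir, "frames")
  tdir <- file.path(out_dir, "tracked")
  if (!file.exists(file.path(fdir, "manifest.json")))
    .data_error("track stage: no frames found (run simulate first)")
  dir.create(tdir, showWarnings = FALSE, recursive = TRUE)
  geom <- .geom_from_config(config)
  trk <- config$track
  window <- if (is.null(trk$window)) 20L else as.integer(trk$window)
  upsampling <- if (is.null(trk$upsampling)) 100L else as.integer(trk$upsampling)
  manifest <- jsonlite::read_json(file.path(fdir, "manifest.json"),
                                  simplifyVector = TRUE)
  dark <- .readChannels(file.path(fdir, "dark.tif"))$intensity
  flats <- lapply(seq_len(manifest$n_raster), function(r)
    readFrame(file.path(fdir, sprintf("flat_r%02d.tif", r))))
  t0 <- Sys.time()
  n_masked <- 0L
  for (ia in seq_len(manifest$n_angles)) {
    maps <- lapply(seq_len(manifest$n_raster), function(r) {
      sf <- readFrame(.frame_path(fdir, ia, r))
      trackFrame(sf, flats[[r]], dark = dark, geom = geom,
                 window = window, upsampling = upsampling)
    })
    n_masked <- n_masked + sum(vapply(maps, function(m)
      sum(is.na(transmissionMap(m))), numeric(1L)))
    st <- stitch(maps, geom, angle = manifest$angles_rad[ia])
    writeStitched(st, file.path(tdir, sprintf("stitched_a%04d.tif", ia)))
  }
  .log_stage("track", "%d angles tracked, %d beamlets masked, %.1f s",
             manifest$n_angles, n_masked,
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  .mark_done(out_dir, "track", config,
             list(window = window, upsampling = upsampling,
                  masked_beamlets = n_masked))
}

.stage_integrate <- function(config, out_dir) {
  tdir <- file.path(out_dir, "tracked")
  pdir <- file.path(out_dir, "phase")
  files <- sort(list.files(tdir, "^stitched_.*\\.tif$", full.names = TRUE))
  if (!length(files))
    .data_error("integrate stage: no stitched projections found")
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  geom <- .geom_from_config(config)
  k <- wavenumber(geom)
  for (f in files) {
    st <- readStitched(f)
    pm <- integrateProjection(st, k)
    writePhaseMap(pm, file.path(pdir, sub("stitched", "phase", basename(f))))
  }
  .log_stage("integrate", "%d phase maps", length(files))
  .mark_done(out_dir, "integrate", config, list(n_maps = length(files)))
}

.stage_reconstruct <- function(config, out_dir) {
  tdir <- file.path(out_dir, "tracked")
  pdir <- file.path(out_dir, "phase")
  rdir <- file.path(out_dir, "recon")
  sfiles <- sort(list.files(tdir, "^stitched_.*\\.tif$", full.names = TRUE))
  pfiles <- sort(list.files(pdir, "^phase_.*\\.tif$", full.names = TRUE))
  if (!length(sfiles) || !length(pfiles))
    .data_error("reconstruct stage: missing stitched or phase inputs")
  dir.create(rdir, showWarnings = FALSE, recursive = TRUE)
  geom <- .geom_from_config(config)
  k <- wavenumber(geom)
  projections <- lapply(sfiles, readStitched)
  phases <- lapply(pfiles, readPhaseMap)
  ## air strips at the lateral edges, same width rule as the phase anchor
  nc <- ncol(phaseShift(phases[[1L]]))
  w <- max(1L, nc %/% 16L)
  air <- c(seq_len(w), nc - seq_len(w) + 1L)
  vol_mu <- fbpReconstruct(attenuationSinogram(projections), "mu")
  vol_de <- fbpReconstruct(phaseSinogram(phases, k, air_cols = air), "delta")
  writeVolume(vol_mu, file.path(rdir, "mu.tif"))
  writeVolume(vol_de, file.path(rdir, "delta.tif"))
  hp <- splitHalfDatasets(projections)
  hq <- splitHalfDatasets(phases)
  writeVolume(fbpReconstruct(attenuationSinogram(hp$first), "mu"),
              file.path(rdir, "mu_half1.tif"))
  writeVolume(fbpReconstruct(attenuationSinogram(hp$second), "mu"),
              file.path(rdir, "mu_half2.tif"))
  writeVolume(fbpReconstruct(phaseSinogram(hq$first, k, air_cols = air),
                             "delta"),
              file.path(rdir, "delta_half1.tif"))
  writeVolume(fbpReconstruct(phaseSinogram(hq$second, k, air_cols = air),
                             "delta"),
              file.path(rdir, "delta_half2.tif"))
  .log_stage("reconstruct", "mu and delta volumes (+ half splits) from %d angles",
             length(projections))
  .mark_done(out_dir, "reconstruct", config,
             list(n_angles = length(projections)))
}

.stage_metrics <- function(config, out_dir) {
  rdir <- file.path(out_dir, "recon")
  tdir <- file.path(out_dir, "tracked")
  mdir <- file.path(out_dir, "metrics")
  if (!file.exists(file.path(rdir, "mu_half1.tif")))
    .data_error("metrics stage: missing half-dataset reconstructions")
  dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list()
  ny <- dim(voxels(readVolume(file.path(rdir, "mu_half1.tif"))))[1L]
  for (chn in c("mu", "delta")) {
    v1 <- readVolume(file.path(rdir, sprintf("%s_half1.tif", chn)))
    v2 <- readVolume(file.path(rdir, sprintf("%s_half2.tif", chn)))
    curve <- if (ny >= 5L) frcAveraged(v1, v2) else
      frc(matrix(voxels(v1)[1L, , ], dim(voxels(v1))[2L]),
          matrix(voxels(v2)[1L, , ], dim(voxels(v2))[2L]),
          pitch = voxelSize(v1))
    writeFRCCurve(curve, file.path(mdir, sprintf("frc_%s.csv", chn)))
    summary[[paste0("frc_", chn)]] <- list(
      crossing_freq = crossingFreq(curve),
      resolution_um = if (is.na(resolution(curve))) "sampling-limited"
                      else resolution(curve) * 1e6)
  }
  sfiles <- sort(list.files(tdir, "^stitched_.*\\.tif$", full.names = TRUE))
  if (length(sfiles)) {
    st <- readStitched(sfiles[[1L]])
    amap <- alphaX(st)
    shape <- config$metrics$sensitivity_window
    if (is.null(shape)) shape <- c(8L, 8L)
    wins <- tileWindows(dim(amap), n = 8L, shape = shape)
    est <- tryCatch(angularSensitivity(amap, wins), error = function(e) NULL)
    if (!is.null(est))
      summary$sensitivity <- list(sigma_alpha_nrad = sigmaMean(est) * 1e9,
                                  sem_nrad = sigmaSem(est) * 1e9)
  }
  jsonlite::write_json(summary, file.path(mdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_stage("metrics", "summary written")
  .mark_done(out_dir, "metrics", config, list())
}

#' Run the beam-tracking pipeline
#'
#' Executes simulate -> track -> integrate -> reconstruct -> metrics into
#' an artifact directory. Each stage writes a done-marker with provenance
#' (config hash, seed, package version); stages whose marker already
#' exists are skipped, so the pipeline is idempotent and resumable:
#' deleting one stage's outputs and marker re-runs only that stage and
#' the ones after it were their markers also removed. Deterministic given
#' the seeds in the config.
#'
#' @param config configuration list, or path to a YAML file with sections
#'   `geometry`, `simulate` (`phantom`, `n_projections`, `flux`, `seed`),
#'   `track` (`window`, `upsampling`) and optional `metrics`
#' @param out_dir artifact directory (created if needed)
#' @param stages subset of stages to consider, in pipeline order
#' @return `out_dir`, invisibly
#' @export
runPipeline <- function(config, out_dir,
                        stages = c("simulate", "track", "integrate",
                                   "reconstruct", "metrics")) {
  if (is.character(config)) {
    if (!file.exists(config)) .cfg_error("config file not found")
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .cfg_error("config must be a list or a YAML path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_stages <- c(simulate = .stage_simulate, track = .stage_track,
                  integrate = .stage_integrate,
                  reconstruct = .stage_reconstruct,
                  metrics = .stage_metrics)
  stages <- match.arg(stages, names(all_stages), several.ok = TRUE)
  for (s in names(all_stages)) {
    if (!s %in% stages) next
    if (file.exists(.stage_marker(out_dir, s))) {
      .log_stage(s, "already done, skipping")
      next
    }
    all_stages[[s]](config, out_dir)
  }
  invisible(out_dir)
}
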