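## hc in keV.nm (CODATA); converts photon energy to vacuum wavelength.
.hc_keV_nm <- 1.23984198

.unit_to_m <- c(m = 1, cm = 1e-2, mm = 1e-3, um = 1e-6, nm = 1e-9)

.as_metres <- function(value, unit, field) {
  if (!unit %in% names(.unit_to_m))
    stop(sprintf("unknown length unit '%s' for '%s' (use m, cm, mm, um, nm)",
                 unit, field), call. = FALSE)
  value * .unit_to_m[[unit]]
}

#' Construct the set-up geometry
#'
#' Boundary units follow the way such a set-up is usually quoted:
#' propagation distance in metres, pitches and apertures in micrometres.
#' Internally everything is stored in metres.
#'
#' @param z_od object-to-detector distance (m)
#' @param mean_energy mean photon energy (keV)
#' @param pixel_size effective detector pixel pitch (um)
#' @param modulator_period modulator aperture pitch (um)
#' @param aperture_diameter front-face aperture diameter (um)
#' @param n_subpitch raster steps per period per axis (integer >= 1)
#' @return a [SetupGeometry-class] object
#' @examples
#' geom <- SetupGeometry(z_od = 1.28, mean_energy = 27, pixel_size = 2.6,
#'                       modulator_period = 50, aperture_diameter = 15,
#'                       n_subpitch = 8)
#' samplingPitch(geom) * 1e6   # 6.25 um
#' @export
SetupGeometry <- function(z_od, mean_energy, pixel_size = 2.6,
                          modulator_period = 50, aperture_diameter = 15,
                          n_subpitch = 1L) {
  new("SetupGeometry",
      zOd = as.numeric(z_od), meanEnergy = as.numeric(mean_energy),
      pixelSize = as.numeric(pixel_size) * 1e-6,
      modulatorPeriod = as.numeric(modulator_period) * 1e-6,
      apertureDiameter = as.numeric(aperture_diameter) * 1e-6,
      nSubpitch = as.integer(n_subpitch))
}

#' Photon energy to vacuum wavenumber
#'
#' k = 2 pi E / (hc) with hc = 1.23984198 keV nm, i.e. the wavenumber that
#' enters the small-angle relation between beamlet displacement and the
#' phase-shift gradient.
#'
#' @param energy photon energy (keV), positive
#' @return wavenumber k (1/m)
#' @examples
#' energyToWavenumber(16)   # ~8.108e10 1/m
#' @export
energyToWavenumber <- function(energy) {
  if (!is.numeric(energy) || any(!is.finite(energy)) || any(energy <= 0))
    stop("'energy' must be positive and finite (keV)", call. = FALSE)
  2 * pi * energy / (.hc_keV_nm * 1e-9)
}

#' @rdname accessors
#' @details `wavenumber(geom)` returns the vacuum wavenumber of the
#'   geometry's mean energy (1/m).
#' @export
setGeneric("wavenumber", function(x) standardGeneric("wavenumber"))

#' @rdname accessors
setMethod("wavenumber", "SetupGeometry",
          function(x) energyToWavenumber(x@meanEnergy))

#' Sub-pitch sampling pitch
#'
#' The lateral sampling of the stitched images: modulator period divided by
#' the number of raster steps per period.
#'
#' @param geom a [SetupGeometry-class]
#' @return sampling pitch (m)
#' @export
samplingPitch <- function(geom) {
  stopifnot(is(geom, "SetupGeometry"))
  geom@modulatorPeriod / geom@nSubpitch
}

#' Total exposure time of a raster-scanned tomography
#'
#' @param n_projections number of rotation angles
#' @param n_raster number of modulator raster positions (e.g. 8 x 8 = 64)
#' @param t_frame exposure per frame (s)
#' @return total exposure (hours)
#' @examples
#' scanExposure(1200, 64, 0.15)   # 3.2 h
#' @export
scanExposure <- function(n_projections, n_raster, t_frame) {
  if (any(c(n_projections, n_raster, t_frame) <= 0))
    stop("all scan-plan factors must be positive", call. = FALSE)
  n_projections * n_raster * t_frame / 3600
}

#' Read a set-up geometry from a YAML config
#'
#' Expected keys match the [SetupGeometry-class] field names
#' (`z_od`, `mean_energy`, `pixel_size`, `modulator_period`,
#' `aperture_diameter`, `n_subpitch`). Length units are declared in an
#' optional `units:` mapping (field -> one of m, cm, mm, um, nm); fields
#' without a declared unit default to metres for `z_od` and micrometres
#' for the pitches and the aperture. Energy is always keV.
#'
#' @param path path to a YAML file
#' @return a [SetupGeometry-class]
#' @export
readGeometry <- function(path) {
  cfg <- yaml::read_yaml(path)
  req <- c("z_od", "mean_energy", "pixel_size", "modulator_period")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("geometry config missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  units <- cfg$units
  defaults <- c(z_od = "m", pixel_size = "um", modulator_period = "um",
                aperture_diameter = "um")
  len_m <- function(field) {
    u <- if (!is.null(units[[field]])) units[[field]] else defaults[[field]]
    .as_metres(as.numeric(cfg[[field]]), u, field)
  }
  ap <- if (is.null(cfg$aperture_diameter)) 15e-6 else len_m("aperture_diameter")
  ns <- if (is.null(cfg$n_subpitch)) 1L else as.integer(cfg$n_subpitch)
  new("SetupGeometry",
      zOd = len_m("z_od"), meanEnergy = as.numeric(cfg$mean_energy),
      pixelSize = len_m("pixel_size"),
      modulatorPeriod = len_m("modulator_period"),
      apertureDiameter = ap, nSubpitch = ns)
}

#' Write a set-up geometry to YAML
#'
#' Inverse of [readGeometry()]: lengths are written in the default
#' boundary units (z_od in m, pitches in um) with an explicit `units:`
#' block.
#'
#' @param geom a [SetupGeometry-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGeometry <- function(geom, path) {
  stopifnot(is(geom, "SetupGeometry"))
  cfg <- list(
    z_od = geom@zOd, mean_energy = geom@meanEnergy,
    pixel_size = geom@pixelSize * 1e6,
    modulator_period = geom@modulatorPeriod * 1e6,
    aperture_diameter = geom@apertureDiameter * 1e6,
    n_subpitch = geom@nSubpitch,
    units = list(z_od = "m", pixel_size = "um", modulator_period = "um",
                 aperture_diameter = "um"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
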