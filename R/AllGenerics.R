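## Accessor generics. Slots are never accessed with @ from user code.

#' @name accessors
#' @title Accessors for BeamTrack classes
#' @description Read-only accessors for the package's S4 containers. All
#'   lengths are returned in SI units (metres, radians); see the individual
#'   class pages for the meaning of each field.
#' @param x an object of the documented class
#' @return the requested field
NULL

#' @rdname accessors
#' @export
setGeneric("zOd", function(x) standardGeneric("zOd"))
#' @rdname accessors
#' @export
setGeneric("meanEnergy", function(x) standardGeneric("meanEnergy"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("modulatorPeriod", function(x) standardGeneric("modulatorPeriod"))
#' @rdname accessors
#' @export
setGeneric("apertureDiameter", function(x) standardGeneric("apertureDiameter"))
#' @rdname accessors
#' @export
setGeneric("nSubpitch", function(x) standardGeneric("nSubpitch"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("gridPitch", function(x) standardGeneric("gridPitch"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setGeneric("modulatorOffset", function(x) standardGeneric("modulatorOffset"))
#' @rdname accessors
#' @export
setGeneric("deltaMap", function(x) standardGeneric("deltaMap"))
#' @rdname accessors
#' @export
setGeneric("muMap", function(x) standardGeneric("muMap"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("transmissionMap", function(x) standardGeneric("transmissionMap"))
#' @rdname accessors
#' @export
setGeneric("shiftX", function(x) standardGeneric("shiftX"))
#' @rdname accessors
#' @export
setGeneric("shiftY", function(x) standardGeneric("shiftY"))
#' @rdname accessors
#' @export
setGeneric("alphaX", function(x) standardGeneric("alphaX"))
#' @rdname accessors
#' @export
setGeneric("alphaY", function(x) standardGeneric("alphaY"))
#' @rdname accessors
#' @export
setGeneric("rasterOffset", function(x) standardGeneric("rasterOffset"))
#' @rdname accessors
#' @export
setGeneric("projAngle", function(x) standardGeneric("projAngle"))
#' @rdname accessors
#' @export
setGeneric("pitch", function(x) standardGeneric("pitch"))
#' @rdname accessors
#' @export
setGeneric("phaseShift", function(x) standardGeneric("phaseShift"))
#' @rdname accessors
#' @export
setGeneric("sinoData", function(x) standardGeneric("sinoData"))
#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))
#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))
#' @rdname accessors
#' @export
setGeneric("frcFreq", function(x) standardGeneric("frcFreq"))
#' @rdname accessors
#' @export
setGeneric("frcValues", function(x) standardGeneric("frcValues"))
#' @rdname accessors
#' @export
setGeneric("frcThreshold", function(x) standardGeneric("frcThreshold"))
#' @rdname accessors
#' @export
setGeneric("crossingFreq", function(x) standardGeneric("crossingFreq"))
#' @rdname accessors
#' @export
setGeneric("resolution", function(x) standardGeneric("resolution"))
#' @rdname accessors
#' @export
setGeneric("sigmaMean", function(x) standardGeneric("sigmaMean"))
#' @rdname accessors
#' @export
setGeneric("sigmaSem", function(x) standardGeneric("sigmaSem"))

setMethod("zOd", "SetupGeometry", function(x) x@zOd)
setMethod("meanEnergy", "SetupGeometry", function(x) x@meanEnergy)
setMethod("pixelSize", "SetupGeometry", function(x) x@pixelSize)
setMethod("modulatorPeriod", "SetupGeometry", function(x) x@modulatorPeriod)
setMethod("apertureDiameter", "SetupGeometry", function(x) x@apertureDiameter)
setMethod("nSubpitch", "SetupGeometry", function(x) x@nSubpitch)

setMethod("intensity", "BeamletFrame", function(x) x@intensity)
setMethod("gridOrigin", "BeamletFrame", function(x) x@gridOrigin)
setMethod("gridPitch", "BeamletFrame", function(x) x@gridPitch)
setMethod("gridDim", "BeamletFrame", function(x) x@gridDim)
setMethod("modulatorOffset", "BeamletFrame", function(x) x@modulatorOffset)

setMethod("deltaMap", "Phantom", function(x) x@delta)
setMethod("muMap", "Phantom", function(x) x@mu)
setMethod("voxelSize", "Phantom", function(x) x@voxelSize)
setMethod("voxelSize", "Volume", function(x) x@voxelSize)

setMethod("transmissionMap", "TrackingMaps", function(x) x@t)
setMethod("transmissionMap", "StitchedProjection", function(x) x@t)
setMethod("shiftX", "TrackingMaps", function(x) x@dx)
setMethod("shiftY", "TrackingMaps", function(x) x@dy)
setMethod("alphaX", "TrackingMaps", function(x) x@alphaX)
setMethod("alphaY", "TrackingMaps", function(x) x@alphaY)
setMethod("alphaX", "StitchedProjection", function(x) x@alphaX)
setMethod("alphaY", "StitchedProjection", function(x) x@alphaY)
setMethod("rasterOffset", "TrackingMaps", function(x) x@offset)
setMethod("projAngle", "StitchedProjection", function(x) x@angle)
setMethod("projAngle", "PhaseMap", function(x) x@angle)
setMethod("pitch", "StitchedProjection", function(x) x@pitch)
setMethod("pitch", "PhaseMap", function(x) x@pitch)
setMethod("pitch", "Sinogram", function(x) x@pitch)
setMethod("pitch", "FRCCurve", function(x) x@pitch)
setMethod("phaseShift", "PhaseMap", function(x) x@dphi)

setMethod("sinoData", "Sinogram", function(x) x@data)
setMethod("angles", "Sinogram", function(x) x@angles)
setMethod("voxels", "Volume", function(x) x@voxels)
setMethod("channel", "Volume", function(x) x@channel)

setMethod("frcFreq", "FRCCurve", function(x) x@freq)
setMethod("frcValues", "FRCCurve", function(x) x@frc)
setMethod("frcThreshold", "FRCCurve", function(x) x@threshold)
setMethod("crossingFreq", "FRCCurve", function(x) x@crossingFreq)
setMethod("resolution", "FRCCurve", function(x) x@resolution)

setMethod("sigmaMean", "SensitivityEstimate", function(x) x@sigmaMean)
setMethod("sigmaSem", "SensitivityEstimate", function(x) x@sigmaSem)

setMethod("show", "SetupGeometry", function(object) {
  cat("SetupGeometry\n")
  cat(sprintf("  z_od: %.4g m | energy: %.4g keV | pixel: %.3g um\n",
              object@zOd, object@meanEnergy, object@pixelSize * 1e6))
  cat(sprintf("  modulator period: %.3g um | aperture: %.3g um | %d sub-pitch steps (%.4g um sampling)\n",
              object@modulatorPeriod * 1e6, object@apertureDiameter * 1e6,
              object@nSubpitch, object@modulatorPeriod / object@nSubpitch * 1e6))
})

setMethod("show", "BeamletFrame", function(object) {
  cat(sprintf("BeamletFrame: %d x %d px, %d x %d beamlets, pitch %.3g px\n",
              nrow(object@intensity), ncol(object@intensity),
              object@gridDim[2L], object@gridDim[1L], object@gridPitch))
  cat(sprintf("  modulator offset (%.3g, %.3g) um\n",
              object@modulatorOffset[1L] * 1e6, object@modulatorOffset[2L] * 1e6))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@delta)
  cat(sprintf("Phantom: %d x %d x %d voxels [y, x, z], %.3g um pitch\n",
              d[1L], d[2L], d[3L], object@voxelSize * 1e6))
  cat(sprintf("  delta in [%.3g, %.3g], mu in [%.3g, %.3g] 1/m\n",
              min(object@delta), max(object@delta),
              min(object@mu), max(object@mu)))
})

setMethod("show", "TrackingMaps", function(object) {
  cat(sprintf("TrackingMaps: %d x %d beamlets, %d masked\n",
              nrow(object@t), ncol(object@t), sum(is.na(object@t))))
})

setMethod("show", "StitchedProjection", function(object) {
  cat(sprintf("StitchedProjection: %d x %d px at %.4g um, angle %.4g deg\n",
              nrow(object@t), ncol(object@t), object@pitch * 1e6,
              object@angle * 180 / pi))
})

setMethod("show", "PhaseMap", function(object) {
  cat(sprintf("PhaseMap: %d x %d px at %.4g um, range [%.4g, %.4g] rad\n",
              nrow(object@dphi), ncol(object@dphi), object@pitch * 1e6,
              min(object@dphi), max(object@dphi)))
})

setMethod("show", "Sinogram", function(object) {
  d <- dim(object@data)
  cat(sprintf("Sinogram: %d angles x %d rows x %d detector px at %.4g um\n",
              d[1L], d[2L], d[3L], object@pitch * 1e6))
})

setMethod("show", "Volume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Volume (%s): %d x %d x %d voxels at %.4g um\n",
              object@channel, d[1L], d[2L], d[3L], object@voxelSize * 1e6))
})

setMethod("show", "FRCCurve", function(object) {
  cat(sprintf("FRCCurve: %d rings\n", length(object@freq)))
  if (is.na(object@crossingFreq)) {
    cat("  no threshold crossing: resolution is sampling-limited\n")
  } else {
    cat(sprintf("  3-sigma crossing at %.3g cycles/px", object@crossingFreq))
    if (!is.na(object@resolution))
      cat(sprintf(" -> %.3g um", object@resolution * 1e6))
    cat("\n")
  }
})

setMethod("show", "SensitivityEstimate", function(object) {
  cat(sprintf("SensitivityEstimate: %.4g +/- %.2g nrad (%d windows of %d x %d)\n",
              object@sigmaMean * 1e9, object@sigmaSem * 1e9, object@nWindows,
              object@windowShape[1L], object@windowShape[2L]))
})
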