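#' @import methods
NULL

## All internal lengths are stored in metres; micrometres appear only at the
## constructor / file-format boundary. This avoids silent unit mix-ups between
## detector pixels (um), propagation distances (m) and wavenumbers (1/m).

#' Experimental geometry of a two-directional beam-tracking set-up
#'
#' Holds the distances, photon energy and pitches that the retrieval and
#' simulation stages share: the object-to-detector propagation distance, the
#' mean photon energy of the (pink) beam, the effective detector pixel size,
#' the period and front-face aperture diameter of the amplitude modulator,
#' and the number of sub-pitch raster steps per period and axis.
#'
#' @slot zOd object-to-detector distance (m)
#' @slot meanEnergy mean photon energy (keV)
#' @slot pixelSize effective detector pixel pitch (m)
#' @slot modulatorPeriod aperture pitch of the modulator (m)
#' @slot apertureDiameter front-face aperture diameter (m)
#' @slot nSubpitch raster steps per period per axis
#' @seealso [SetupGeometry()] for the user constructor (micrometre boundary
#'   units), [samplingPitch()], [wavenumber()]
#' @export
setClass("SetupGeometry",
  representation(
    zOd = "numeric", meanEnergy = "numeric", pixelSize = "numeric",
    modulatorPeriod = "numeric", apertureDiameter = "numeric",
    nSubpitch = "integer"
  )
)

setValidity("SetupGeometry", function(object) {
  msg <- character()
  for (s in c("zOd", "meanEnergy", "pixelSize", "modulatorPeriod",
              "apertureDiameter")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
  }
  if (length(object@nSubpitch) != 1L || is.na(object@nSubpitch) ||
      object@nSubpitch < 1L)
    msg <- c(msg, "'nSubpitch' must be an integer >= 1")
  if (length(msg)) msg else TRUE
})

#' One detector frame of an array of beamlets
#'
#' A 2D intensity image holding a regular grid of beamlet spots, together
#' with the layout of that grid on the pixel array: the position of the
#' first beamlet centre, the beamlet spacing in pixels, the number of
#' beamlets per axis, and the sub-pitch modulator displacement that was
#' applied when the frame was acquired (or simulated).
#'
#' @slot intensity numeric matrix of pixel counts (rows = y, cols = x)
#' @slot gridOrigin centre of beamlet (1, 1) in pixels, c(x, y); may be
#'   fractional
#' @slot gridPitch beamlet spacing in pixels (may be fractional)
#' @slot gridDim number of beamlets c(nx, ny)
#' @slot modulatorOffset sub-pitch displacement applied, c(x, y), metres
#' @export
setClass("BeamletFrame",
  representation(
    intensity = "matrix", gridOrigin = "numeric", gridPitch = "numeric",
    gridDim = "integer", modulatorOffset = "numeric"
  )
)

setValidity("BeamletFrame", function(object) {
  msg <- character()
  if (any(object@intensity < 0, na.rm = TRUE))
    msg <- c(msg, "intensity must be non-negative")
  if (length(object@gridOrigin) != 2L) msg <- c(msg, "gridOrigin must be c(x, y)")
  if (length(object@gridPitch) != 1L || object@gridPitch <= 0)
    msg <- c(msg, "gridPitch must be a single positive number")
  if (length(object@gridDim) != 2L || any(object@gridDim < 1L))
    msg <- c(msg, "gridDim must be two positive integers")
  if (length(object@modulatorOffset) != 2L)
    msg <- c(msg, "modulatorOffset must be c(x, y)")
  if (length(msg)) msg else TRUE
})

#' Voxelized phantom of refractive-index decrement and attenuation
#'
#' Ground-truth object for the simulator: isotropic voxel grids of the
#' refractive-index decrement delta (dimensionless) and the linear
#' attenuation coefficient mu (1/m). Arrays are indexed
#' \code{[y, x, z]}: y is the rotation axis (volume slices), the beam runs
#' along z at zero rotation, and x is the detector's horizontal axis.
#'
#' @slot delta 3D array of delta, dimensionless, >= 0
#' @slot mu 3D array of mu (1/m), >= 0
#' @slot voxelSize isotropic voxel pitch (m)
#' @export
setClass("Phantom",
  representation(delta = "array", mu = "array", voxelSize = "numeric")
)

setValidity("Phantom", function(object) {
  msg <- character()
  if (length(dim(object@delta)) != 3L || length(dim(object@mu)) != 3L)
    msg <- c(msg, "delta and mu must be 3D arrays [y, x, z]")
  else if (!identical(dim(object@delta), dim(object@mu)))
    msg <- c(msg, "delta and mu must share the same shape")
  if (any(object@delta < 0) || any(object@mu < 0))
    msg <- c(msg, "delta and mu must be non-negative everywhere")
  if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
    msg <- c(msg, "voxelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Per-beamlet retrieval maps for one frame
#'
#' One value per beamlet: transmission (windowed intensity ratio),
#' displacement in pixels along x and y, and the refraction angles derived
#' from the displacements through the geometry. Beamlets that could not be
#' tracked (window off the detector, dead or constant window, non-positive
#' flat signal) are NA in every channel.
#'
#' @slot t transmission map (rows = beamlet y index, cols = x index)
#' @slot dx,dy beamlet displacement maps (pixels)
#' @slot alphaX,alphaY refraction-angle maps (rad)
#' @slot offset modulator raster offset of the tracked frame, c(x, y), m
#' @export
setClass("TrackingMaps",
  representation(
    t = "matrix", dx = "matrix", dy = "matrix",
    alphaX = "matrix", alphaY = "matrix", offset = "numeric"
  )
)

setValidity("TrackingMaps", function(object) {
  d <- dim(object@t)
  for (s in c("dx", "dy", "alphaX", "alphaY"))
    if (!identical(dim(slot(object, s)), d))
      return("all maps must share the same shape")
  if (any(object@t <= 0, na.rm = TRUE))
    return("tracked transmission values must be positive (untracked are NA)")
  TRUE
})

#' Sub-pitch stitched projection
#'
#' Transmission and two refraction-angle images at the sub-pitch sampling
#' resolution, obtained by interleaving the per-beamlet maps of all raster
#' positions of one rotation angle.
#'
#' @slot t,alphaX,alphaY stitched maps (rows = y, cols = x)
#' @slot angle rotation angle (rad)
#' @slot pitch lateral sampling pitch (m), i.e. modulator period / nSubpitch
#' @export
setClass("StitchedProjection",
  representation(
    t = "matrix", alphaX = "matrix", alphaY = "matrix",
    angle = "numeric", pitch = "numeric"
  )
)

setValidity("StitchedProjection", function(object) {
  d <- dim(object@t)
  if (!identical(dim(object@alphaX), d) || !identical(dim(object@alphaY), d))
    return("t, alphaX, alphaY must share the same shape")
  if (object@pitch <= 0) return("pitch must be positive")
  TRUE
})

#' Integrated phase-shift map
#'
#' Phase shift (rad) recovered by Fourier-space integration of the two
#' orthogonal phase gradients. The field is defined up to an additive
#' constant; it is anchored to mean zero over a declared background region.
#'
#' @slot dphi phase-shift map (rad)
#' @slot pitch lateral sampling (m)
#' @slot angle rotation angle of the parent projection (rad)
#' @export
setClass("PhaseMap",
  representation(dphi = "matrix", pitch = "numeric", angle = "numeric")
)

setValidity("PhaseMap", function(object) {
  if (any(!is.finite(object@dphi))) return("dphi must be finite everywhere")
  if (object@pitch <= 0) return("pitch must be positive")
  TRUE
})

#' Sinogram of line integrals
#'
#' Stack of projections arranged (angle, detector row, detector column),
#' holding line integrals of mu (dimensionless entries, -log t) or of delta
#' (entries in metres, -dphi/k).
#'
#' @slot data 3D array (angle, row, col); finite
#' @slot angles rotation angles (rad), strictly increasing in [0, pi)
#' @slot pitch detector sampling pitch (m)
#' @export
setClass("Sinogram",
  representation(data = "array", angles = "numeric", pitch = "numeric")
)

setValidity("Sinogram", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array (angle, row, col)")
  else if (dim(object@data)[1L] != length(object@angles))
    msg <- c(msg, "first dimension of data must match length(angles)")
  if (length(object@angles) && (is.unsorted(object@angles, strictly = TRUE) ||
      any(object@angles < 0) || any(object@angles >= pi)))
    msg <- c(msg, "angles must be strictly increasing within [0, pi)")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data must be finite (inpaint masked bins first)")
  if (length(msg)) msg else TRUE
})

#' Reconstructed volume
#'
#' Voxel map of mu (1/m) or delta (dimensionless), indexed
#' \code{[y, x, z]} with y along the rotation axis. The voxel pitch equals
#' the projection sampling pitch.
#'
#' @slot voxels 3D array [y, x, z]
#' @slot voxelSize isotropic voxel pitch (m)
#' @slot channel "mu" or "delta"
#' @export
setClass("Volume",
  representation(voxels = "array", voxelSize = "numeric", channel = "character")
)

setValidity("Volume", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
  if (any(!is.finite(object@voxels))) return("voxels must be finite")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  TRUE
})

#' Fourier ring correlation curve
#'
#' Per-ring normalized cross-spectrum of two independent images, the
#' 3-sigma noise threshold per ring, and the threshold crossing translated
#' to a real-space resolution. When the curve never falls below the
#' threshold the resolution is sampling-limited and \code{crossingFreq} and
#' \code{resolution} are NA.
#'
#' @slot freq ring spatial frequencies (cycles/pixel)
#' @slot frc correlation per ring, in [-1, 1] up to noise
#' @slot threshold 3-sigma threshold per ring, 3/sqrt(N/2)
#' @slot nPix pixels per ring
#' @slot crossingFreq first threshold crossing (cycles/pixel) or NA
#' @slot pitch real-space pixel pitch (m; NA if unknown)
#' @slot resolution pitch / crossingFreq (m), NA when sampling-limited
#' @export
setClass("FRCCurve",
  representation(
    freq = "numeric", frc = "numeric", threshold = "numeric",
    nPix = "numeric", crossingFreq = "numeric", pitch = "numeric",
    resolution = "numeric"
  )
)

setValidity("FRCCurve", function(object) {
  n <- length(object@freq)
  if (length(object@frc) != n || length(object@threshold) != n ||
      length(object@nPix) != n)
    return("freq, frc, threshold, nPix must have equal length")
  if (any(object@threshold <= 0)) return("threshold must be positive")
  TRUE
})

#' Angular-sensitivity estimate
#'
#' Mean and standard error, over several sample-free windows, of the
#' standard deviation of the measured refraction angles. The mean is the
#' smallest resolvable refraction angle of the set-up.
#'
#' @slot sigmaMean mean per-window std of the refraction angle (rad)
#' @slot sigmaSem standard error of that std across windows (rad)
#' @slot windowShape window extent c(rows, cols) in map pixels
#' @slot nWindows number of windows used
#' @export
setClass("SensitivityEstimate",
  representation(
    sigmaMean = "numeric", sigmaSem = "numeric",
    windowShape = "integer", nWindows = "integer"
  )
)

setValidity("SensitivityEstimate", function(object) {
  msg <- character()
  if (object@sigmaMean < 0) msg <- c(msg, "sigmaMean must be >= 0")
  if (object@sigmaSem < 0) msg <- c(msg, "sigmaSem must be >= 0")
  if (object@nWindows < 2L) msg <- c(msg, "nWindows must be >= 2")
  if (length(msg)) msg else TRUE
})
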