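## Characterization metrics: angular sensitivity from sample-free windows
## of a refraction-angle map, beamlet-pattern visibility, log-log trend
## fits, and Fourier ring correlation with the 3-sigma resolution
## criterion.

#' Angular sensitivity from sample-free windows
#'
#' The smallest resolvable refraction angle, estimated as the mean, over
#' several declared sample-free windows, of the per-window standard
#' deviation of the refraction-angle map; the spread across windows gives
#' the standard error of that estimate.
#'
#' @param alpha_map refraction-angle map (rad)
#' @param windows list of windows, each `c(row, col, nrows, ncols)`
#'   (1-based top-left corner and extent)
#' @return a [SensitivityEstimate-class]; windows containing non-finite
#'   values are excluded with a warning
#' @export
angularSensitivity <- function(alpha_map, windows) {
  stopifnot(is.matrix(alpha_map), length(windows) >= 2L)
  stds <- rep(NA_real_, length(windows))
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    stopifnot(length(win) == 4L)
    rows <- win[1L]:(win[1L] + win[3L] - 1L)
    cols <- win[2L]:(win[2L] + win[4L] - 1L)
    if (min(rows) < 1L || max(rows) > nrow(alpha_map) ||
        min(cols) < 1L || max(cols) > ncol(alpha_map))
      stop("sensitivity window outside the map", call. = FALSE)
    patch <- alpha_map[rows, cols]
    if (any(!is.finite(patch))) {
      warning(sprintf("window %d contains masked values; excluded", w))
      next
    }
    stds[w] <- stats::sd(patch)
  }
  stds <- stds[!is.na(stds)]
  if (length(stds) < 2L)
    stop("fewer than two usable windows", call. = FALSE)
  shape <- as.integer(windows[[1L]][3:4])
  new("SensitivityEstimate",
      sigmaMean = mean(stds),
      sigmaSem = stats::sd(stds) / sqrt(length(stds)),
      windowShape = shape, nWindows = length(stds))
}

#' Evenly spaced rectangular windows across a map
#'
#' Helper that lays out `n` non-overlapping windows of a given shape along
#' the longer axis of a map, for use with [angularSensitivity()] on
#' sample-free (e.g. empty-beam) maps.
#'
#' @param map_dim map size `c(rows, cols)`
#' @param n number of windows
#' @param shape window extent `c(rows, cols)`
#' @return list of `c(row, col, nrows, ncols)` windows
#' @export
tileWindows <- function(map_dim, n = 8L, shape = c(5L, 40L)) {
  shape <- pmin(as.integer(shape), as.integer(map_dim))
  along_rows <- map_dim[1L] >= map_dim[2L]
  span <- if (along_rows) map_dim[1L] else map_dim[2L]
  ext <- if (along_rows) shape[1L] else shape[2L]
  starts <- round(seq(1L, span - ext + 1L, length.out = n))
  lapply(starts, function(s) {
    if (along_rows) c(s, 1L, shape[1L], shape[2L])
    else c(1L, s, shape[1L], shape[2L])
  })
}

#' Visibility of the beamlet illumination pattern
#'
#' Folds the flat frame by the beamlet period in both directions into one
#' average unit cell and reports `(I_max - I_min) / (I_max + I_min)` with
#' robust (1st/99th percentile) extrema of the folded cell.
#'
#' @param frame a [BeamletFrame-class], or a numeric matrix together with
#'   `pitch_px` and `origin_px`
#' @param pitch_px beamlet period (px), ignored for a BeamletFrame
#' @param origin_px grid origin c(x, y) px, ignored for a BeamletFrame
#' @return visibility in \[0, 1\]; 0 for a constant frame
#' @export
visibility <- function(frame, pitch_px = NULL, origin_px = c(0, 0)) {
  if (is(frame, "BeamletFrame")) {
    img <- frame@intensity
    pitch_px <- frame@gridPitch
    origin_px <- frame@gridOrigin
  } else {
    img <- frame
    stopifnot(!is.null(pitch_px))
  }
  nb <- max(4L, round(pitch_px))
  ri <- ((row(img) - origin_px[2L]) %% pitch_px) / pitch_px
  ci <- ((col(img) - origin_px[1L]) %% pitch_px) / pitch_px
  bin <- pmin(floor(ri * nb), nb - 1L) * nb + pmin(floor(ci * nb), nb - 1L)
  cell <- tapply(as.vector(img), bin, mean)
  q <- stats::quantile(cell, c(0.01, 0.99), names = FALSE)
  if (q[2L] + q[1L] <= 0 || q[2L] == q[1L]) return(0)
  (q[2L] - q[1L]) / (q[2L] + q[1L])
}

#' Fit a power law y = c * x^p in log-log space
#'
#' Ordinary least squares of log(y) on log(x); used for the sensitivity
#' trends versus propagation distance (expected exponent -1) and versus
#' number of averaged frames (expected exponent -1/2).
#'
#' @param x,y positive numeric vectors, length >= 3
#' @return list with `exponent` and `prefactor`
#' @export
fitPowerLaw <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    stop("need at least three (x, y) pairs", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("power-law fit requires positive data", call. = FALSE)
  fit <- stats::lm(log(y) ~ log(x))
  list(exponent = unname(stats::coef(fit)[2L]),
       prefactor = exp(unname(stats::coef(fit)[1L])))
}

#' Empty-beam refraction-angle noise
#'
#' Simulates a sample-free acquisition (the "sample" frames see no
#' object) at the given geometry and flux, tracks it against a
#' high-statistics flat reference, and returns the standard deviation of
#' the recovered refraction angles over the beamlet grid: the
#' angular-sensitivity floor of the configuration. Averaging `n_frames`
#' sample frames before tracking emulates longer exposure; with photon
#' (Poisson) noise dominant the returned sigma scales as `1/z_od` with
#' propagation distance and as `n_frames^-1/2` with exposure.
#'
#' @param geom a [SetupGeometry-class]
#' @param grid_dim beamlets per axis c(nx, ny)
#' @param flux expected photons per beamlet per frame
#' @param n_frames number of frames averaged before tracking
#' @param seed RNG seed
#' @param window analysis window (px)
#' @param upsampling registration upsampling factor
#' @param sigma_px beamlet width (px)
#' @return standard deviation of the refraction angle (rad), pooled over
#'   both axes and all beamlets
#' @export
emptyBeamSigma <- function(geom, grid_dim = c(12L, 12L), flux = 1000,
                           n_frames = 1L, seed = 1L, window = 12L,
                           upsampling = 100L, sigma_px = 2) {
  stopifnot(is(geom, "SetupGeometry"), n_frames >= 1L)
  ref <- simulateFlat(geom, grid_dim, flux = Inf, sigma_px = sigma_px)
  acc <- NULL
  for (f in seq_len(n_frames)) {
    fr <- simulateFlat(geom, grid_dim, flux = flux,
                       seed = seed + 977L * f, sigma_px = sigma_px)
    acc <- if (is.null(acc)) intensity(fr) else acc + intensity(fr)
  }
  frame <- ref
  frame@intensity <- acc / n_frames
  ## scale the unit-amplitude noiseless reference to the same mean level
  ref@intensity <- ref@intensity * flux
  tm <- trackFrame(frame, ref, dark = NULL, geom = geom,
                   window = window, upsampling = upsampling)
  stats::sd(c(alphaX(tm), alphaY(tm)), na.rm = TRUE)
}

## Ring assignment of the unshifted FFT grid: ring r collects Fourier
## pixels whose radial frequency index rounds to r, r = 0..floor(N/2).
.ring_index <- function(nr, nc) {
  fr <- 0:(nr - 1); fr[fr > nr / 2] <- fr[fr > nr / 2] - nr
  fc <- 0:(nc - 1); fc[fc > nc / 2] <- fc[fc > nc / 2] - nc
  round(sqrt(outer(fr^2, fc^2, "+")))
}

#' Fourier ring correlation of two independent images
#'
#' Per ring of one Fourier-pixel width,
#' `FRC(r) = |sum_r F1 conj(F2)| / sqrt(sum_r |F1|^2 sum_r |F2|^2)`,
#' with the 3-sigma noise threshold `3 / sqrt(N(r)/2)` for a ring of N
#' pixels. The resolution is the real-space length corresponding to the
#' lowest frequency at which the curve first falls below the threshold
#' (scanning outward from DC, which is excluded; linear interpolation
#' between rings); if the curve never falls below the threshold the
#' resolution is sampling-limited.
#'
#' @param im1,im2 same-shape real images (independent noise realizations)
#' @param pitch real-space pixel pitch (m), NA if unknown
#' @return an [FRCCurve-class]
#' @export
frc <- function(im1, im2, pitch = NA_real_) {
  if (!identical(dim(im1), dim(im2)))
    stop("FRC inputs must have the same shape", call. = FALSE)
  nr <- nrow(im1); nc <- ncol(im1)
  F1 <- stats::fft(im1)
  F2 <- stats::fft(im2)
  ring <- .ring_index(nr, nc)
  rmax <- floor(min(nr, nc) / 2)
  keep <- ring <= rmax
  rvec <- factor(ring[keep], levels = 0:rmax)
  num <- F1 * Conj(F2)
  sums <- rowsum(cbind(Re(num)[keep], Im(num)[keep],
                       (Mod(F1)^2)[keep], (Mod(F2)^2)[keep]),
                 rvec)
  npix <- as.numeric(table(rvec))
  denom <- sqrt(sums[, 3L] * sums[, 4L])
  frc_r <- ifelse(denom > 0, sqrt(sums[, 1L]^2 + sums[, 2L]^2) / denom,
                  NA_real_)
  freq <- (0:rmax) / min(nr, nc)
  thr <- 3 / sqrt(pmax(npix, 1) / 2)
  .frc_curve(freq, frc_r, thr, npix, pitch)
}

## Assemble an FRCCurve: find the first below-threshold crossing by
## outward scan (DC excluded, NA rings skipped), with linear
## interpolation between rings. The innermost rings hold so few Fourier
## pixels that the 3-sigma threshold exceeds 1 there, so the scan starts
## at the first ring where the curve is above the threshold; a curve that
## never rises above it (pure noise) crosses at the first scanned ring.
.frc_curve <- function(freq, frc_r, thr, npix, pitch) {
  crossing <- NA_real_
  nr <- length(freq)
  above <- which(is.finite(frc_r[-1L]) & frc_r[-1L] >= thr[-1L]) + 1L
  if (!length(above)) {
    crossing <- freq[2L]
  } else if (above[1L] < nr) {
    for (r in (above[1L] + 1L):nr) {
      if (!is.finite(frc_r[r])) next
      if (frc_r[r] < thr[r]) {
        prev <- r - 1L
        if (is.finite(frc_r[prev]) && frc_r[prev] >= thr[prev]) {
          d0 <- unname(frc_r[prev] - thr[prev])
          d1 <- unname(frc_r[r] - thr[r])
          tt <- d0 / (d0 - d1)
          crossing <- freq[prev] + tt * (freq[r] - freq[prev])
        } else crossing <- freq[r]
        break
      }
    }
  }
  res <- if (!is.na(crossing) && !is.na(pitch)) pitch / crossing
         else NA_real_
  new("FRCCurve", freq = freq, frc = as.numeric(frc_r),
      threshold = as.numeric(thr), nPix = as.numeric(npix),
      crossingFreq = crossing, pitch = as.numeric(pitch),
      resolution = res)
}

#' Slice-averaged Fourier ring correlation of two half-volumes
#'
#' Computes the single-slice FRC for each of five (or more) adjacent
#' slices from the middle of the two independently reconstructed
#' volumes, averages the curves ring by ring, and applies the 3-sigma
#' threshold and crossing search to the averaged curve. Averaging
#' reduces the ring-to-ring variance of the estimate.
#'
#' @param vol1,vol2 [Volume-class] objects (or 3D arrays `[y, x, z]`) of
#'   the two half-dataset reconstructions
#' @param slice_indices indices of >= 5 adjacent slices along y; NULL
#'   takes the five middle slices
#' @return an [FRCCurve-class]
#' @export
frcAveraged <- function(vol1, vol2, slice_indices = NULL) {
  a1 <- if (is(vol1, "Volume")) voxels(vol1) else vol1
  a2 <- if (is(vol2, "Volume")) voxels(vol2) else vol2
  p <- if (is(vol1, "Volume")) voxelSize(vol1) else NA_real_
  stopifnot(identical(dim(a1), dim(a2)))
  ny <- dim(a1)[1L]
  if (is.null(slice_indices)) {
    mid <- ceiling(ny / 2)
    slice_indices <- (mid - 2L):(mid + 2L)
  }
  if (length(slice_indices) < 5L)
    stop("slice-averaged FRC needs at least five slices", call. = FALSE)
  if (any(diff(sort(slice_indices)) != 1L))
    stop("slices must be adjacent", call. = FALSE)
  if (min(slice_indices) < 1L || max(slice_indices) > ny)
    stop("slice indices outside the volume", call. = FALSE)
  curves <- lapply(slice_indices, function(y)
    frc(matrix(a1[y, , ], dim(a1)[2L], dim(a1)[3L]),
        matrix(a2[y, , ], dim(a1)[2L], dim(a1)[3L]), pitch = p))
  fr_mat <- vapply(curves, frcValues, numeric(length(frcFreq(curves[[1L]]))))
  mean_frc <- rowMeans(fr_mat)
  c1 <- curves[[1L]]
  .frc_curve(frcFreq(c1), mean_frc, frcThreshold(c1), c1@nPix, p)
}

#' Translate an FRC threshold crossing into a spatial resolution
#'
#' @param crossing_freq crossing frequency (cycles/pixel), in (0, 0.5];
#'   NA means the curve never crossed the threshold, i.e. the resolution
#'   is sampling-limited (at least as good as the sampling pitch) and NA
#'   is returned
#' @param pitch real-space pixel pitch (m)
#' @return resolution `pitch / crossing_freq` (m)
#' @examples
#' crossingToResolution(0.4, 6.25e-6) * 1e6   # 15.625 um (~16 um)
#' @export
crossingToResolution <- function(crossing_freq, pitch) {
  stopifnot(pitch > 0)
  if (is.na(crossing_freq)) return(NA_real_)
  if (crossing_freq <= 0 || crossing_freq > 0.5)
    stop("crossing frequency must be in (0, 0.5] cycles/pixel",
         call. = FALSE)
  pitch / crossing_freq
}
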