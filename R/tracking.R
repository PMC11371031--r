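## Retrieval core: per-beamlet transmission and subpixel displacement
## against flat frames, conversion to refraction angles through the set-up
## geometry, and interleaving of sub-pitch raster positions into fully
## sampled maps.

#' Extract the analysis window of one beamlet
#'
#' Returns the `window x window` patch centred on the *nominal* beamlet
#' grid position (not the refracted position); windows of neighbouring
#' beamlets may overlap when the grid pitch is smaller than the window.
#'
#' @param frame a [BeamletFrame-class]
#' @param i,j beamlet index: row (y) and column (x), 1-based
#' @param window window side (px)
#' @return numeric matrix, or NULL when the window would cross the frame
#'   edge (the beamlet is flagged missing, never clipped)
#' @export
extractWindow <- function(frame, i, j, window = 20L) {
  stopifnot(is(frame, "BeamletFrame"))
  gd <- frame@gridDim
  if (i < 1L || i > gd[2L] || j < 1L || j > gd[1L])
    stop("beamlet index out of grid", call. = FALSE)
  xc <- frame@gridOrigin[1L] + (j - 1) * frame@gridPitch
  yc <- frame@gridOrigin[2L] + (i - 1) * frame@gridPitch
  cols <- seq(round(xc) - floor((window - 1) / 2), length.out = window)
  rows <- seq(round(yc) - floor((window - 1) / 2), length.out = window)
  img <- frame@intensity
  if (rows[1L] < 1L || cols[1L] < 1L ||
      rows[window] > nrow(img) || cols[window] > ncol(img))
    return(NULL)
  img[rows, cols, drop = FALSE]
}

#' Windowed transmission of one beamlet
#'
#' t = (sum of sample-window intensities) / (sum of flat-window
#' intensities).
#'
#' @param sample_patch,flat_patch same-shape numeric matrices
#' @return transmission (dimensionless); NA when the flat sum is not
#'   positive (invalid beamlet)
#' @export
transmission <- function(sample_patch, flat_patch) {
  stopifnot(identical(dim(sample_patch), dim(flat_patch)))
  s0 <- sum(flat_patch)
  if (!is.finite(s0) || s0 <= 0) return(NA_real_)
  sum(sample_patch) / s0
}

## Matrix-multiply DFT: evaluates the cross-correlation
## cc(tau) = (1/N) sum_f R[f] exp(+2 pi i f . tau) on a fine tau grid of
## step 1/usfac centred on tau0 (the upsampled refinement step of the
## single-step upsampled cross-correlation algorithm).
.dftups <- function(R, tau0, usfac, nhalf) {
  nr <- nrow(R); nc <- ncol(R)
  fr <- 0:(nr - 1); fr[fr > nr / 2] <- fr[fr > nr / 2] - nr
  fc <- 0:(nc - 1); fc[fc > nc / 2] <- fc[fc > nc / 2] - nc
  taur <- tau0[1L] + (-nhalf:nhalf) / usfac
  tauc <- tau0[2L] + (-nhalf:nhalf) / usfac
  kr <- exp(2i * pi * outer(taur, fr) / nr)
  kc <- exp(2i * pi * outer(fc, tauc) / nc)
  list(cc = Re(kr %*% R %*% kc) / (nr * nc), taur = taur, tauc = tauc)
}

#' Subpixel registration of a beamlet against its flat reference
#'
#' Single-step upsampled cross-correlation: the integer-pixel displacement
#' is found from the FFT cross-correlation peak, then refined by
#' evaluating the cross-correlation on a `1/upsampling`-pixel grid in a
#' +/- 1.5 px neighbourhood with a matrix-multiply DFT. Precision is the
#' registration quantum `1/upsampling` px.
#'
#' Sign convention: positive `dx` means the sample beamlet moved toward
#' +x (increasing column) on the detector relative to the flat.
#'
#' @param sample_patch,flat_patch same-shape, non-constant matrices
#' @param upsampling upsampling factor (integer >= 1)
#' @return c(dx, dy) in pixels, or c(NA, NA) for a constant (beamlet-free)
#'   patch
#' @export
registerSubpixel <- function(sample_patch, flat_patch, upsampling = 100L) {
  stopifnot(identical(dim(sample_patch), dim(flat_patch)), upsampling >= 1)
  if (stats::sd(sample_patch) == 0 || stats::sd(flat_patch) == 0)
    return(c(dx = NA_real_, dy = NA_real_))
  nr <- nrow(sample_patch); nc <- ncol(sample_patch)
  R <- stats::fft(sample_patch) * Conj(stats::fft(flat_patch))
  cc <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  pk <- which.max(cc)
  pr <- (pk - 1L) %% nr
  pc <- (pk - 1L) %/% nr
  if (pr > nr / 2) pr <- pr - nr
  if (pc > nc / 2) pc <- pc - nc
  if (upsampling > 1) {
    nhalf <- ceiling(0.75 * upsampling)
    up <- .dftups(R, c(pr, pc), upsampling, nhalf)
    pk <- which.max(up$cc)
    ir <- (pk - 1L) %% nrow(up$cc) + 1L
    ic <- (pk - 1L) %/% nrow(up$cc) + 1L
    return(c(dx = up$tauc[ic], dy = up$taur[ir]))
  }
  c(dx = as.numeric(pc), dy = as.numeric(pr))
}

#' Convert beamlet displacements to refraction angles
#'
#' Under the small-angle, geometrical-optics approximation a beamlet
#' displaced by d pixels at the detector has been refracted by
#' `alpha = d * pixel_size / z_od`.
#'
#' @param dx,dy displacements (px); scalars or same-shape arrays
#' @param geom a [SetupGeometry-class]
#' @return list with `alpha_x`, `alpha_y` (rad)
#' @export
toRefraction <- function(dx, dy, geom) {
  stopifnot(is(geom, "SetupGeometry"))
  s <- geom@pixelSize / geom@zOd
  list(alpha_x = dx * s, alpha_y = dy * s)
}

#' Track every beamlet of a sample frame against its flat
#'
#' Dark-subtracts both frames, then for each beamlet of the grid computes
#' the windowed transmission and the subpixel displacement, and converts
#' displacements to refraction angles. Beamlets whose window leaves the
#' detector, whose flat signal is not positive, or whose window carries no
#' structure are masked (NA in every map).
#'
#' @param sample_frame,flat_frame [BeamletFrame-class] objects on the same
#'   grid
#' @param dark matrix of dark counts (same size as the frames), or NULL
#' @param geom a [SetupGeometry-class]
#' @param window analysis window side (px)
#' @param upsampling registration upsampling factor
#' @return a [TrackingMaps-class]
#' @export
trackFrame <- function(sample_frame, flat_frame, dark = NULL, geom,
                       window = 20L, upsampling = 100L) {
  stopifnot(is(sample_frame, "BeamletFrame"), is(flat_frame, "BeamletFrame"))
  if (!isTRUE(all.equal(sample_frame@gridOrigin, flat_frame@gridOrigin,
                        tolerance = 1e-6)) ||
      !isTRUE(all.equal(sample_frame@gridPitch, flat_frame@gridPitch,
                        tolerance = 1e-9)) ||
      !identical(sample_frame@gridDim, flat_frame@gridDim))
    stop("sample and flat frames are on different beamlet grids",
         call. = FALSE)
  s_img <- sample_frame@intensity
  f_img <- flat_frame@intensity
  if (!is.null(dark)) {
    stopifnot(identical(dim(dark), dim(s_img)), identical(dim(dark), dim(f_img)))
    s_img <- pmax(s_img - dark, 0)
    f_img <- pmax(f_img - dark, 0)
  }
  sfr <- sample_frame; sfr@intensity <- s_img
  ffr <- flat_frame; ffr@intensity <- f_img
  nbx <- sample_frame@gridDim[1L]; nby <- sample_frame@gridDim[2L]
  tm <- dxm <- dym <- matrix(NA_real_, nby, nbx)
  for (i in seq_len(nby)) {
    for (j in seq_len(nbx)) {
      ps <- extractWindow(sfr, i, j, window)
      pf <- extractWindow(ffr, i, j, window)
      if (is.null(ps) || is.null(pf)) next
      tt <- transmission(ps, pf)
      if (is.na(tt) || tt <= 0) next
      if (stats::sd(ps) == 0 || stats::sd(pf) == 0) next
      d <- registerSubpixel(ps, pf, upsampling)
      if (any(is.na(d))) next
      tm[i, j] <- tt
      dxm[i, j] <- d[[1L]]
      dym[i, j] <- d[[2L]]
    }
  }
  al <- toRefraction(dxm, dym, geom)
  new("TrackingMaps", t = tm, dx = dxm, dy = dym,
      alphaX = al$alpha_x, alphaY = al$alpha_y,
      offset = as.numeric(sample_frame@modulatorOffset))
}

#' Stitch sub-pitch raster maps into a fully sampled projection
#'
#' Interleaves the per-beamlet maps of all `n^2` raster positions: output
#' pixel `(i*n + b, j*n + a)` (row, col; 0-based) comes from the beamlet
#' `(i, j)` of the map whose modulator offset occupies sub-pitch slot
#' `(a, b)`, so increasing modulator offset along +x fills increasing
#' output x.
#'
#' @param maps list of [TrackingMaps-class], one per raster position, each
#'   carrying its modulator offset
#' @param geom a [SetupGeometry-class]; `nSubpitch(geom)^2` maps are
#'   required with distinct offsets on the sub-pitch lattice
#' @param angle rotation angle to record (rad)
#' @return a [StitchedProjection-class] at `samplingPitch(geom)` resolution
#' @export
stitch <- function(maps, geom, angle = NA_real_) {
  stopifnot(is(geom, "SetupGeometry"))
  n <- geom@nSubpitch
  sp <- samplingPitch(geom)
  if (length(maps) != n * n)
    stop(sprintf("need exactly %d maps for an %d x %d raster", n * n, n, n),
         call. = FALSE)
  slots <- t(vapply(maps, function(m) {
    s <- rasterOffset(m) / sp
    if (any(abs(s - round(s)) > 1e-6))
      stop("raster offset not on the sub-pitch lattice", call. = FALSE)
    round(s)
  }, numeric(2L)))
  if (any(slots < 0) || any(slots >= n))
    stop("raster offsets outside the sub-pitch lattice", call. = FALSE)
  key <- slots[, 1L] + n * slots[, 2L]
  if (anyDuplicated(key))
    stop("duplicate raster offsets", call. = FALSE)
  d0 <- dim(transmissionMap(maps[[1L]]))
  out_t <- out_ax <- out_ay <- matrix(NA_real_, d0[1L] * n, d0[2L] * n)
  for (m in maps) {
    a <- round(rasterOffset(m)[1L] / sp)
    b <- round(rasterOffset(m)[2L] / sp)
    rows <- seq(b + 1L, by = n, length.out = d0[1L])
    cols <- seq(a + 1L, by = n, length.out = d0[2L])
    out_t[rows, cols] <- transmissionMap(m)
    out_ax[rows, cols] <- alphaX(m)
    out_ay[rows, cols] <- alphaY(m)
  }
  new("StitchedProjection", t = out_t, alphaX = out_ax, alphaY = out_ay,
      angle = as.numeric(angle), pitch = sp)
}

#' Undo sub-pitch stitching
#'
#' Inverse permutation of [stitch()]: recovers the per-raster-position
#' beamlet maps from a stitched projection.
#'
#' @param stitched a [StitchedProjection-class]
#' @param geom the [SetupGeometry-class] used for stitching
#' @return list of [TrackingMaps-class] (displacement channels NA: they
#'   are not stored in a stitched projection)
#' @export
unstitch <- function(stitched, geom) {
  stopifnot(is(stitched, "StitchedProjection"), is(geom, "SetupGeometry"))
  n <- geom@nSubpitch
  sp <- samplingPitch(geom)
  tmat <- transmissionMap(stitched)
  stopifnot(nrow(tmat) %% n == 0L, ncol(tmat) %% n == 0L)
  out <- vector("list", n * n)
  idx <- 1L
  for (b in 0:(n - 1)) {
    for (a in 0:(n - 1)) {
      rows <- seq(b + 1L, nrow(tmat), by = n)
      cols <- seq(a + 1L, ncol(tmat), by = n)
      nab <- matrix(NA_real_, length(rows), length(cols))
      out[[idx]] <- new("TrackingMaps",
                        t = tmat[rows, cols, drop = FALSE],
                        dx = nab, dy = nab,
                        alphaX = alphaX(stitched)[rows, cols, drop = FALSE],
                        alphaY = alphaY(stitched)[rows, cols, drop = FALSE],
                        offset = c(a, b) * sp)
      idx <- idx + 1L
    }
  }
  out
}

#' Locate the beamlet grid on a flat frame
#'
#' Estimates the regular beamlet lattice from a raw flat image: the frame
#' is collapsed to row and column mean profiles, smoothed over roughly
#' half a period, local maxima are taken as beamlet centres, and a
#' straight line fitted through centre position versus index yields the
#' origin and pitch of the best-fit regular lattice per axis.
#'
#' @param img numeric matrix (a flat frame's intensity)
#' @param approx_pitch approximate beamlet spacing (px)
#' @return list with `origin` c(x, y) px, `pitch` px (mean of the two
#'   axes), `dim` c(nx, ny)
#' @export
locateGrid <- function(img, approx_pitch) {
  axis_fit <- function(profile) {
    w <- max(3L, round(approx_pitch / 2))
    if (w %% 2L == 0L) w <- w + 1L
    sm <- stats::filter(profile, rep(1 / w, w), sides = 2)
    sm[is.na(sm)] <- 0
    n <- length(sm)
    half <- floor(approx_pitch / 2)
    peaks <- which(vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      sm[i] == max(sm[lo:hi]) && sm[i] > mean(sm)
    }, logical(1L)))
    ## collapse plateaus of equal smoothed value into one centre
    if (length(peaks) > 1L) {
      grp <- cumsum(c(1L, diff(peaks) > half))
      peaks <- round(tapply(peaks, grp, mean))
    }
    if (length(peaks) < 2L)
      stop("could not locate at least two beamlets along an axis",
           call. = FALSE)
    fit <- stats::lm(peaks ~ seq_along(peaks))
    c(origin = sum(stats::coef(fit)), pitch = stats::coef(fit)[[2L]],
      n = length(peaks))
  }
  fx <- axis_fit(colMeans(img))
  fy <- axis_fit(rowMeans(img))
  list(origin = c(fx[["origin"]], fy[["origin"]]),
       pitch = mean(c(fx[["pitch"]], fy[["pitch"]])),
       dim = c(as.integer(fx[["n"]]), as.integer(fy[["n"]])))
}

#' Wrap a raw image as a BeamletFrame
#'
#' @param img numeric matrix of counts
#' @param grid layout as returned by [locateGrid()]
#' @param offset modulator offset c(x, y), metres
#' @return a [BeamletFrame-class]
#' @export
asBeamletFrame <- function(img, grid, offset = c(0, 0)) {
  new("BeamletFrame", intensity = img, gridOrigin = grid$origin,
      gridPitch = grid$pitch, gridDim = as.integer(grid$dim),
      modulatorOffset = as.numeric(offset))
}
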