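## Synthetic-data generator: geometrical-optics forward model of a
## two-directional beam-tracking acquisition. A phantom of (delta, mu) voxels
## is projected along parallel rays; each modulator aperture produces a
## Gaussian beamlet on the detector whose amplitude is scaled by the local
## transmission and whose centre is displaced by z_od * alpha, with
## alpha = grad(Phi)/k the refraction angle. Poisson counting noise is added.

#' Construct a phantom from delta and mu voxel arrays
#'
#' @param delta 3D array `[y, x, z]` of refractive-index decrement (>= 0)
#' @param mu 3D array of linear attenuation coefficient (1/m, >= 0)
#' @param voxel_size isotropic voxel pitch (um)
#' @return a [Phantom-class]
#' @export
Phantom <- function(delta, mu, voxel_size) {
  if (is.matrix(delta)) delta <- array(delta, c(1L, dim(delta)))
  if (is.matrix(mu)) mu <- array(mu, c(1L, dim(mu)))
  new("Phantom", delta = delta, mu = mu,
      voxelSize = as.numeric(voxel_size) * 1e-6)
}

#' Extruded-disc (cylinder) phantom
#'
#' Builds a phantom of one or more cylinders extruded along the rotation
#' axis (y), each defined by a centre, radius, delta and mu. Discs are
#' painted in order, later discs overwriting earlier ones, so nested
#' two-material objects are easy to set up. Voxels are classified by their
#' centre, which leaves a one-voxel-soft edge after projection -- a
#' realistic stand-in for the finite source/optic blur of a real system.
#'
#' @param n lateral grid size (the x-z plane is n x n voxels)
#' @param n_slices extent along the rotation axis (y)
#' @param voxel_size voxel pitch (um)
#' @param discs data.frame with columns `cx`, `cz` (centre offsets from the
#'   grid centre, voxels), `radius` (voxels), `delta`, `mu` (1/m)
#' @param edge_sigma Gaussian width (voxels) used to band-limit the
#'   material interfaces; 0 keeps hard voxel-classified edges. Smooth
#'   interfaces make the phantom resolvable by a finite sampling pitch,
#'   which is what a calibration object should be.
#' @return a [Phantom-class]
#' @export
cylinderPhantom <- function(n, n_slices = 1L, voxel_size,
                            discs = data.frame(cx = 0, cz = 0,
                                               radius = n / 4,
                                               delta = 1e-7, mu = 30),
                            edge_sigma = 0) {
  ctr <- (n + 1) / 2
  xs <- (1:n) - ctr
  d2 <- matrix(0, n, n)   # [x, z]
  m2 <- matrix(0, n, n)
  for (r in seq_len(nrow(discs))) {
    rr <- outer((xs - discs$cx[r])^2, (xs - discs$cz[r])^2, "+")
    inside <- rr <= discs$radius[r]^2
    d2[inside] <- discs$delta[r]
    m2[inside] <- discs$mu[r]
  }
  if (edge_sigma > 0) {
    d2 <- .gauss_blur(d2, edge_sigma)
    m2 <- .gauss_blur(m2, edge_sigma)
    d2[d2 < 0] <- 0
    m2[m2 < 0] <- 0
  }
  delta <- aperm(array(d2, c(n, n, n_slices)), c(3L, 1L, 2L))
  mu <- aperm(array(m2, c(n, n, n_slices)), c(3L, 1L, 2L))
  new("Phantom", delta = delta, mu = mu,
      voxelSize = as.numeric(voxel_size) * 1e-6)
}

## FFT Gaussian blur of a matrix (periodic; callers keep the object away
## from the grid border).
.gauss_blur <- function(m, sigma) {
  nr <- nrow(m); nc <- ncol(m)
  fr <- 0:(nr - 1); fr[fr > nr / 2] <- fr[fr > nr / 2] - nr
  fc <- 0:(nc - 1); fc[fc > nc / 2] <- fc[fc > nc / 2] - nc
  H <- exp(-2 * pi^2 * sigma^2 *
             (outer((fr / nr)^2, (fc / nc)^2, "+")))
  Re(stats::fft(stats::fft(m) * H, inverse = TRUE)) / (nr * nc)
}

## Bilinear interpolation of matrix f at fractional 1-based indices
## (xi rows, zi cols); zero outside the grid.
.bilinear <- function(f, xi, zi) {
  nr <- nrow(f); nc <- ncol(f)
  x0 <- floor(xi); z0 <- floor(zi)
  wx <- xi - x0; wz <- zi - z0
  ok <- x0 >= 1 & x0 <= nr - 1 & z0 >= 1 & z0 <= nc - 1
  out <- numeric(length(xi))
  if (any(ok)) {
    x0k <- x0[ok]; z0k <- z0[ok]; wxk <- wx[ok]; wzk <- wz[ok]
    i00 <- x0k + (z0k - 1) * nr
    v <- f[i00]       * (1 - wxk) * (1 - wzk) +
         f[i00 + 1]   * wxk       * (1 - wzk) +
         f[i00 + nr]  * (1 - wxk) * wzk +
         f[i00 + nr + 1] * wxk    * wzk
    out[ok] <- v
  }
  dim(out) <- dim(xi)
  out
}

## Parallel-beam line integrals of one [x, z] slice at one angle.
## p(u) = sum_s f(cx + u cos - s sin, cz + u sin + s cos), in voxel units;
## detector coordinate u spans the slice width at voxel pitch.
.radon2d <- function(f, angle) {
  n <- nrow(f)
  ctr <- (n + 1) / 2
  us <- (1:n) - ctr
  ns <- ceiling(n * sqrt(2)) + 2L
  ss <- seq(-ns / 2, ns / 2, by = 1)
  ca <- cos(angle); sa <- sin(angle)
  xi <- outer(us * ca, -ss * sa, "+") + ctr
  zi <- outer(us * sa, ss * ca, "+") + ctr
  rowSums(.bilinear(f, xi, zi))
}

#' Project a phantom at one rotation angle
#'
#' Parallel-beam line integrals of mu and delta along rays at the given
#' angle, sampled on the phantom's own (fine) grid: transmission
#' `t = exp(-integral mu dl)`, phase shift `dphi = -k integral delta dl`,
#' and the two orthogonal gradients of `dphi` by central differences on
#' the projection grid.
#'
#' @param phantom a [Phantom-class]
#' @param angle rotation angle (rad)
#' @param k vacuum wavenumber (1/m), e.g. [energyToWavenumber()]
#' @return list with matrices `t`, `dphi`, `gx`, `gy` (rows = y, cols =
#'   detector x) and the sampling `pitch` (m)
#' @export
projectPhantom <- function(phantom, angle, k) {
  stopifnot(is(phantom, "Phantom"))
  d <- dim(phantom@delta)
  ny <- d[1L]; n <- d[2L]
  if (d[2L] != d[3L])
    stop("phantom must be square in the x-z plane", call. = FALSE)
  h <- phantom@voxelSize
  Amu <- matrix(0, ny, n)
  Ade <- matrix(0, ny, n)
  for (y in seq_len(ny)) {
    Amu[y, ] <- .radon2d(matrix(phantom@mu[y, , ], n, n), angle) * h
    Ade[y, ] <- .radon2d(matrix(phantom@delta[y, , ], n, n), angle) * h
  }
  tmap <- exp(-Amu)
  dphi <- -k * Ade
  g <- .grad2d(dphi, h)
  list(t = tmap, dphi = dphi, gx = g$gx, gy = g$gy, pitch = h)
}

## Central differences (one-sided at borders); x along columns, y along rows.
.grad2d <- function(f, h) {
  nr <- nrow(f); nc <- ncol(f)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nc >= 3) {
    gx[, 2:(nc - 1)] <- (f[, 3:nc, drop = FALSE] -
                         f[, 1:(nc - 2), drop = FALSE]) / (2 * h)
    gx[, 1] <- (f[, 2] - f[, 1]) / h
    gx[, nc] <- (f[, nc] - f[, nc - 1]) / h
  } else if (nc == 2) gx[] <- (f[, 2] - f[, 1]) / h
  if (nr >= 3) {
    gy[2:(nr - 1), ] <- (f[3:nr, , drop = FALSE] -
                         f[1:(nr - 2), , drop = FALSE]) / (2 * h)
    gy[1, ] <- (f[2, ] - f[1, ]) / h
    gy[nr, ] <- (f[nr, ] - f[nr - 1, ]) / h
  } else if (nr == 2) gy[] <- (f[2, ] - f[1, ]) / h
  list(gx = gx, gy = gy)
}

#' Render an array of Gaussian beamlets into a detector frame
#'
#' Each beamlet is an isotropic Gaussian spot of width `sigma_px` whose
#' total expected count is `flux * t` and whose centre is displaced by
#' `z_od * alpha / pixel_size` pixels with `alpha = g / k`, i.e. the
#' geometrical-optics response to the local phase gradient. Per-beamlet
#' inputs `t_image`, `gradx`, `grady` are sampled at the beamlet grid (one
#' value per beamlet). Poisson noise is drawn with the given seed; pass
#' `flux = Inf` for a noiseless frame of unit beamlet intensity.
#'
#' @param t_image per-beamlet transmission matrix (rows = beamlet y index)
#' @param gradx,grady per-beamlet phase gradients (rad/m)
#' @param geom a [SetupGeometry-class]
#' @param flux expected photons per beamlet (positive; Inf = noiseless)
#' @param seed RNG seed for the Poisson draw (NULL = no noise)
#' @param offset modulator displacement applied, c(x, y), metres; shifts
#'   both the beamlet grid on the detector and the recorded offset
#' @param sigma_px Gaussian beamlet width (px)
#' @param margin_px clear border around the beamlet grid (px)
#' @return a [BeamletFrame-class]
#' @export
renderBeamlets <- function(t_image, gradx, grady, geom, flux = 1e4,
                           seed = NULL, offset = c(0, 0), sigma_px = 2,
                           margin_px = NULL) {
  stopifnot(is(geom, "SetupGeometry"))
  if (!is.matrix(t_image)) t_image <- as.matrix(t_image)
  if (!is.matrix(gradx)) gradx <- as.matrix(gradx)
  if (!is.matrix(grady)) grady <- as.matrix(grady)
  stopifnot(identical(dim(t_image), dim(gradx)),
            identical(dim(t_image), dim(grady)))
  if (length(flux) != 1L || is.na(flux) || flux <= 0)
    stop("'flux' must be a single positive number", call. = FALSE)
  nby <- nrow(t_image); nbx <- ncol(t_image)
  pitch_px <- geom@modulatorPeriod / geom@pixelSize
  if (is.null(margin_px)) margin_px <- ceiling(6 * sigma_px + pitch_px)
  k <- wavenumber(geom)
  ## displacement in px for unit gradient: z_od / (k * pixel_size)
  disp <- geom@zOd / (k * geom@pixelSize)
  off_px <- offset / geom@pixelSize
  x0 <- margin_px + pitch_px / 2 + off_px[1L]
  y0 <- margin_px + pitch_px / 2 + off_px[2L]
  ## frame size is offset-independent so that all raster positions share a
  ## detector grid (the margin absorbs sub-pitch displacements < one period)
  npx <- ceiling(nbx * pitch_px + 2 * margin_px)
  npy <- ceiling(nby * pitch_px + 2 * margin_px)
  amp0 <- (if (is.finite(flux)) flux else 1) / (2 * pi * sigma_px^2)
  img <- matrix(0, npy, npx)
  rad <- ceiling(6 * sigma_px)
  for (iy in seq_len(nby)) {
    for (ix in seq_len(nbx)) {
      tt <- t_image[iy, ix]
      xc <- x0 + (ix - 1) * pitch_px + disp * gradx[iy, ix]
      yc <- y0 + (iy - 1) * pitch_px + disp * grady[iy, ix]
      cl <- max(1L, floor(xc) - rad):min(npx, ceiling(xc) + rad)
      rw <- max(1L, floor(yc) - rad):min(npy, ceiling(yc) + rad)
      gx <- exp(-((cl - xc)^2) / (2 * sigma_px^2))
      gy <- exp(-((rw - yc)^2) / (2 * sigma_px^2))
      img[rw, cl] <- img[rw, cl] + (amp0 * tt) * outer(gy, gx)
    }
  }
  if (is.finite(flux) && !is.null(seed)) {
    set.seed(seed)
    img[] <- stats::rpois(length(img), img)
  }
  new("BeamletFrame", intensity = img, gridOrigin = c(x0, y0),
      gridPitch = pitch_px, gridDim = c(nbx, nby),
      modulatorOffset = as.numeric(offset))
}

#' Simulate a flat frame (no sample)
#'
#' @param geom a [SetupGeometry-class]
#' @param grid_dim beamlets per axis, c(nx, ny)
#' @param flux expected photons per beamlet
#' @param seed RNG seed (NULL = noiseless)
#' @param offset modulator displacement c(x, y), metres
#' @param sigma_px beamlet Gaussian width (px)
#' @return a [BeamletFrame-class]
#' @export
simulateFlat <- function(geom, grid_dim, flux = 1e4, seed = NULL,
                         offset = c(0, 0), sigma_px = 2) {
  z <- matrix(0, grid_dim[2L], grid_dim[1L])
  renderBeamlets(z + 1, z, z, geom, flux = flux, seed = seed,
                 offset = offset, sigma_px = sigma_px)
}

#' Simulate a dark frame
#'
#' Constant detector offset plus Gaussian read noise.
#'
#' @param dims frame size c(rows, cols)
#' @param offset_counts constant offset (counts)
#' @param read_noise Gaussian read-noise sigma (counts)
#' @param seed RNG seed (NULL = noiseless constant frame)
#' @return numeric matrix of counts (clipped at zero)
#' @export
simulateDark <- function(dims, offset_counts = 100, read_noise = 2,
                         seed = NULL) {
  img <- matrix(offset_counts, dims[1L], dims[2L])
  if (!is.null(seed)) {
    set.seed(seed)
    img[] <- pmax(0, img + stats::rnorm(length(img), 0, read_noise))
  }
  img
}

#' Simulate a full raster-scanned tomography acquisition
#'
#' For every rotation angle (equally spaced over \[0, 180) degrees) and
#' every sub-pitch raster position of the modulator, renders a sample
#' beamlet frame from the phantom's projection, plus one flat frame per
#' raster position and a dark frame. Beamlet (i, j) at raster offset
#' (a, b) samples the fine projection grid at pixel
#' (i * n + b, j * n + a), so the set of raster positions tiles the fine
#' grid completely. Per-angle ground-truth maps are returned for oracle
#' comparisons.
#'
#' In `"tomography"` mode the modulator moves (the beamlet grid shifts on
#' the detector); in `"planar"` mode the sample moves instead and the grid
#' stays fixed, with the offset recorded in its modulator-equivalent sign
#' convention so that downstream stitching is identical.
#'
#' @param phantom a [Phantom-class]; its lateral size must be an integer
#'   multiple of `nSubpitch(geom)` and its voxel pitch should equal
#'   `samplingPitch(geom)` for geometric consistency
#' @param geom a [SetupGeometry-class]
#' @param n_projections number of rotation angles
#' @param flux expected photons per beamlet
#' @param seed base RNG seed; per-frame seeds are derived from it
#' @param mode `"tomography"` (modulator raster) or `"planar"` (sample
#'   raster)
#' @param sigma_px beamlet Gaussian width (px)
#' @param noise logical; FALSE renders noiseless frames (dark still
#'   constant)
#' @return list with elements `sample` (list over angles of lists over
#'   raster positions of [BeamletFrame-class]), `flats` (list over raster
#'   positions), `dark` (matrix), `angles` (rad), `truth` (per-angle list
#'   of fine-grid `t`, `dphi`, `gx`, `gy`), `geom`, `offsets` (matrix of
#'   raster offsets, metres)
#' @export
simulateScan <- function(phantom, geom, n_projections, flux = 1e4,
                         seed = 1L, mode = c("tomography", "planar"),
                         sigma_px = 2, noise = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is(phantom, "Phantom"), is(geom, "SetupGeometry"),
            n_projections >= 1)
  n <- geom@nSubpitch
  d <- dim(phantom@delta)
  ny_f <- d[1L]; nx_f <- d[2L]
  if (nx_f %% n != 0L || ny_f %% n != 0L)
    stop("phantom grid must be a multiple of nSubpitch per axis",
         call. = FALSE)
  sp <- samplingPitch(geom)
  if (abs(phantom@voxelSize - sp) > 1e-12 * sp)
    warning("phantom voxel pitch differs from the sub-pitch sampling pitch")
  nbx <- nx_f %/% n; nby <- ny_f %/% n
  k <- wavenumber(geom)
  angles <- (seq_len(n_projections) - 1) * pi / n_projections
  offs <- as.matrix(expand.grid(a = 0:(n - 1), b = 0:(n - 1)))
  fseed <- function(i) if (noise) (seed + i) %% .Machine$integer.max else NULL
  ## every acquired frame sits on the detector's dark background
  add_dark <- function(fr, sd_seed) {
    fr@intensity <- fr@intensity +
      simulateDark(dim(fr@intensity), seed = sd_seed)
    fr
  }
  flats <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    det_off <- if (mode == "tomography") offs[r, ] * sp else c(0, 0)
    flats[[r]] <- simulateFlat(geom, c(nbx, nby),
                               flux = if (noise) flux else Inf,
                               seed = fseed(2L * r), offset = det_off,
                               sigma_px = sigma_px)
    if (noise) flats[[r]] <- add_dark(flats[[r]], fseed(2L * r + 1L))
    ## record the sampling offset regardless of which stage moved
    flats[[r]]@modulatorOffset <- as.numeric(offs[r, ] * sp)
  }
  dark <- simulateDark(dim(intensity(flats[[1L]])), seed = fseed(0L))
  sample_frames <- vector("list", n_projections)
  truth <- vector("list", n_projections)
  cnt <- nrow(offs)
  for (ia in seq_len(n_projections)) {
    pr <- projectPhantom(phantom, angles[ia], k)
    truth[[ia]] <- pr
    per_raster <- vector("list", nrow(offs))
    for (r in seq_len(nrow(offs))) {
      a <- offs[r, 1L]; b <- offs[r, 2L]
      rows <- seq(b + 1L, by = n, length.out = nby)
      cols <- seq(a + 1L, by = n, length.out = nbx)
      det_off <- if (mode == "tomography") c(a, b) * sp else c(0, 0)
      fr <- renderBeamlets(pr$t[rows, cols, drop = FALSE],
                           pr$gx[rows, cols, drop = FALSE],
                           pr$gy[rows, cols, drop = FALSE],
                           geom, flux = if (noise) flux else Inf,
                           seed = fseed(2L * cnt + 2L), offset = det_off,
                           sigma_px = sigma_px)
      if (noise) fr <- add_dark(fr, fseed(2L * cnt + 3L))
      fr@modulatorOffset <- as.numeric(c(a, b) * sp)
      per_raster[[r]] <- fr
      cnt <- cnt + 1L
    }
    sample_frames[[ia]] <- per_raster
  }
  list(sample = sample_frames, flats = flats, dark = dark, angles = angles,
       truth = truth, geom = geom, offsets = offs * sp)
}
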