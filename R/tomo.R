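## Parallel-beam filtered back projection of the attenuation and
## refractive-index-decrement volumes. Sinogram entries are line
## integrals: -log t for mu (dimensionless) and -dphi/k for delta
## (metres). The filter is the discrete Ram-Lak kernel applied by FFT
## convolution with zero padding; back projection uses linear
## interpolation. The centre-of-rotation convention is (n + 1)/2 in
## 1-based detector coordinates throughout the package.

#' Build the attenuation sinogram from stitched projections
#'
#' Entries are -log t. Non-positive or masked transmission values are
#' inpainted by 1D linear interpolation along the detector row (the ramp
#' filter does not tolerate NaN).
#'
#' @param projections list of [StitchedProjection-class], any order; they
#'   are sorted by angle
#' @return a [Sinogram-class] with data (angle, row, col)
#' @export
attenuationSinogram <- function(projections) {
  stopifnot(length(projections) >= 1L,
            all(vapply(projections, is, logical(1L), "StitchedProjection")))
  ang <- vapply(projections, projAngle, numeric(1L))
  ord <- order(ang)
  projections <- projections[ord]
  ang <- ang[ord]
  d <- dim(transmissionMap(projections[[1L]]))
  data <- array(0, c(length(projections), d[1L], d[2L]))
  for (ia in seq_along(projections)) {
    tm <- transmissionMap(projections[[ia]])
    tm[!is.finite(tm) | tm <= 0] <- NA_real_
    s <- -log(tm)
    data[ia, , ] <- .inpaint_rows(s)
  }
  new("Sinogram", data = data, angles = ang,
      pitch = pitch(projections[[1L]]))
}

## Fill NA entries of each row by linear interpolation along the row
## (constant extrapolation at the ends); an all-NA row becomes zero.
.inpaint_rows <- function(m) {
  for (r in seq_len(nrow(m))) {
    v <- m[r, ]
    bad <- !is.finite(v)
    if (!any(bad)) next
    if (all(bad)) { m[r, ] <- 0; next }
    ok <- which(!bad)
    m[r, bad] <- stats::approx(ok, v[ok], xout = which(bad),
                               rule = 2)$y
  }
  m
}

#' Build the refractive-index-decrement sinogram from phase maps
#'
#' Entries are -dphi/k, the line integral of delta in metres. Fourier
#' integration leaves each phase map with a small arbitrary offset (its
#' anchor is estimated from finitely many noisy background pixels);
#' when `air_cols` names detector columns known to be outside the sample
#' at every angle, each sinogram row is re-zeroed on the mean of those
#' columns, which removes the per-projection offset before
#' reconstruction.
#'
#' @param phase_maps list of [PhaseMap-class]
#' @param k vacuum wavenumber (1/m)
#' @param air_cols integer vector of sample-free detector columns, or
#'   NULL to skip the per-row re-zeroing
#' @return a [Sinogram-class]
#' @export
phaseSinogram <- function(phase_maps, k, air_cols = NULL) {
  stopifnot(length(phase_maps) >= 1L,
            all(vapply(phase_maps, is, logical(1L), "PhaseMap")))
  ang <- vapply(phase_maps, projAngle, numeric(1L))
  ord <- order(ang)
  phase_maps <- phase_maps[ord]
  ang <- ang[ord]
  d <- dim(phaseShift(phase_maps[[1L]]))
  data <- array(0, c(length(phase_maps), d[1L], d[2L]))
  for (ia in seq_along(phase_maps)) {
    s <- -phaseShift(phase_maps[[ia]]) / k
    if (!is.null(air_cols))
      s <- s - rowMeans(s[, air_cols, drop = FALSE])
    data[ia, , ] <- s
  }
  new("Sinogram", data = data, angles = ang,
      pitch = pitch(phase_maps[[1L]]))
}

## Discrete Ram-Lak kernel (impulse response of the band-limited ramp):
## h(0) = 1/(4 h^2), h(n) = 0 for even n, -1/(pi^2 n^2 h^2) for odd n.
.ramlak_kernel <- function(L, h) {
  n <- c(0:(L / 2), (-L / 2 + 1):(-1))
  k <- numeric(L)
  k[n == 0] <- 1 / (4 * h^2)
  odd <- n %% 2 != 0
  k[odd] <- -1 / (pi^2 * n[odd]^2 * h^2)
  k
}

## Filter + back-project one sinogram plane (n_angles x n_det).
.fbp2d <- function(P, angle_set, h) {
  na <- nrow(P); nd <- ncol(P)
  L <- 2^ceiling(log2(2 * nd))
  Hf <- stats::fft(.ramlak_kernel(L, h))
  ctr <- (nd + 1) / 2
  xs <- (1:nd) - ctr
  recon <- matrix(0, nd, nd)   # [x, z]
  for (ia in seq_len(na)) {
    p <- c(P[ia, ], numeric(L - nd))
    q <- h * Re(stats::fft(stats::fft(p) * Hf, inverse = TRUE)) / L
    q <- q[seq_len(nd)]
    ca <- cos(angle_set[ia]); sa <- sin(angle_set[ia])
    U <- outer(xs * ca, xs * sa, "+") + ctr
    i0 <- floor(U)
    w <- U - i0
    ok <- i0 >= 1 & i0 <= nd - 1
    vals <- matrix(0, nd, nd)
    vals[ok] <- q[i0[ok]] * (1 - w[ok]) + q[i0[ok] + 1L] * w[ok]
    recon <- recon + vals
  }
  recon * pi / na
}

#' Filtered back projection reconstruction
#'
#' Slice-by-slice parallel-beam FBP with the discrete Ram-Lak (ramp)
#' kernel and linear-interpolation back projection. With line-integral
#' inputs (-log t or -dphi/k) the output voxels estimate mu (1/m) or
#' delta (dimensionless) directly; the reconstruction grid equals the
#' projection grid.
#'
#' @param sino a [Sinogram-class] with at least two angles
#' @param channel label stored in the output ("mu" or "delta")
#' @return a [Volume-class] `[y, x, z]`
#' @export
fbpReconstruct <- function(sino, channel = "mu") {
  stopifnot(is(sino, "Sinogram"))
  d <- dim(sino@data)
  if (d[1L] < 2L)
    stop("FBP needs at least two projection angles", call. = FALSE)
  ny <- d[2L]; nd <- d[3L]
  vol <- array(0, c(ny, nd, nd))
  for (y in seq_len(ny))
    vol[y, , ] <- .fbp2d(matrix(sino@data[, y, ], d[1L], nd),
                         sino@angles, sino@pitch)
  new("Volume", voxels = vol, voxelSize = sino@pitch, channel = channel)
}

#' Split projections into two independent half datasets
#'
#' Alternating assignment by angle index: projections 1, 3, 5, ... form
#' the first half and 2, 4, 6, ... the second; each half keeps its true
#' angles. Used to build the two independent reconstructions that Fourier
#' ring correlation requires.
#'
#' @param projections a list (of projections, phase maps, or anything
#'   indexed by angle), length >= 2
#' @return list with elements `first` and `second`
#' @export
splitHalfDatasets <- function(projections) {
  n <- length(projections)
  if (n < 2L) stop("need at least two projections to split", call. = FALSE)
  list(first = projections[seq(1L, n, by = 2L)],
       second = projections[seq(2L, n, by = 2L)])
}
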