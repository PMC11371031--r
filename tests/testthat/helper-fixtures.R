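## Shared fixtures: a toy geometry small enough for fast tests but with
## the real detector pixel (2.6 um) and a modulator period that is an
## exact multiple of it (31.2 um = 12 px), so windows and pitches stay
## aligned without rounding.

toyGeom <- function(z_od = 1.28, energy = 16, n_subpitch = 2L) {
  SetupGeometry(z_od = z_od, mean_energy = energy, pixel_size = 2.6,
                modulator_period = 31.2, aperture_diameter = 15,
                n_subpitch = n_subpitch)
}

## Analytic Gaussian spot on an n x n pixel grid (pixel-centre sampling).
gaussSpot <- function(n, xc, yc, sigma = 2, amp = 1) {
  X <- col(matrix(0, n, n)); Y <- row(matrix(0, n, n))
  amp * exp(-((X - xc)^2 + (Y - yc)^2) / (2 * sigma^2))
}

## Brute-force registration oracle: scan candidate shifts on a fine grid
## and maximize the plain correlation sum between the sample patch and an
## analytically shifted Gaussian reference. Independent of any FFT path.
## The Gaussian is separable, so the score over a whole (dx, dy) grid is
## the bilinear form Gy' S Gx; the scan is still an exhaustive grid
## search at `step` resolution (coarse pass at 10x, fine pass around the
## winner).
bruteForceShift <- function(sample_patch, xc, yc, sigma = 2,
                            span = 0.6, step = 0.001) {
  n <- nrow(sample_patch)
  px <- 1:n
  scan <- function(dxs, dys) {
    Gx <- vapply(dxs, function(d) exp(-((px - xc - d)^2) / (2 * sigma^2)),
                 numeric(n))
    Gy <- vapply(dys, function(d) exp(-((px - yc - d)^2) / (2 * sigma^2)),
                 numeric(n))
    scores <- t(Gy) %*% sample_patch %*% Gx
    pk <- which(scores == max(scores), arr.ind = TRUE)[1, ]
    c(dx = dxs[pk[2]], dy = dys[pk[1]])
  }
  coarse <- seq(-span, span, by = step * 10)
  b <- scan(coarse, coarse)
  fine <- function(ctr) seq(ctr - step * 12, ctr + step * 12, by = step)
  scan(fine(b["dx"]), fine(b["dy"]))
}

## Two-material extruded-disc phantom matched to a geometry's sampling:
## a large soft disc with a denser inclusion, interfaces band-limited to
## one voxel so the object is resolvable at the sampling pitch.
twoMaterialPhantom <- function(geom, n = 40L, n_slices = 2L) {
  cylinderPhantom(n = n, n_slices = n_slices,
                  voxel_size = samplingPitch(geom) * 1e6,
                  discs = data.frame(cx = c(0, n / 10), cz = c(0, 0.075 * n),
                                     radius = c(0.35 * n, 0.1375 * n),
                                     delta = c(2e-7, 4e-7),
                                     mu = c(1500, 3000)),
                  edge_sigma = 1)
}

## Full simulate -> track -> stitch chain, returning stitched projections
## and the scan (with ground truth). The analysis window equals the
## beamlet pitch (12 px), as in set-ups where the window matches the
## modulator period on the detector.
trackedScan <- function(phantom, geom, n_projections, flux = 2e5,
                        seed = 7L, noise = TRUE, window = 12L,
                        upsampling = 100L) {
  scan <- simulateScan(phantom, geom, n_projections = n_projections,
                       flux = flux, seed = seed, noise = noise)
  dark <- if (noise) scan$dark else NULL
  projs <- lapply(seq_along(scan$angles), function(ia) {
    maps <- lapply(seq_along(scan$flats), function(r)
      trackFrame(scan$sample[[ia]][[r]], scan$flats[[r]], dark = dark,
                 geom = geom, window = window, upsampling = upsampling))
    stitch(maps, geom, angle = scan$angles[ia])
  })
  list(projs = projs, scan = scan)
}
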