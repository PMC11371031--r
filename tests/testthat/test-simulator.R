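test_that("phantom projection matches closed-form line integrals", {
  g <- toyGeom()
  k <- wavenumber(g)
  sp <- samplingPitch(g)
  ## uniform block: mu chosen so the straight-through path gives 0.1.
  ## Voxels are point samples of the field, so a uniform slab of n
  ## voxels spans the n - 1 intervals between its outer voxel centres.
  n <- 16L
  path_m <- (n - 1L) * sp
  mu_val <- 0.1 / path_m
  ph <- Phantom(delta = array(0, c(1, n, n)),
                mu = array(mu_val, c(1, n, n)),
                voxel_size = sp * 1e6)
  pr <- projectPhantom(ph, 0, k)
  ## interior rays traverse the full block
  expect_equal(pr$t[1, 8], exp(-0.1), tolerance = 1e-6)
  expect_true(all(pr$gx == 0))
  ## delta-only disc: centre phase is -k * delta * chord
  del <- 3e-7
  phd <- cylinderPhantom(n = 32, n_slices = 1, voxel_size = sp * 1e6,
                         discs = data.frame(cx = 0, cz = 0, radius = 10,
                                            delta = del, mu = 0))
  prd <- projectPhantom(phd, 0, k)
  chord <- 2 * 10 * sp
  expect_equal(min(prd$dphi), -k * del * chord, tolerance = 0.06)
  expect_true(all(prd$t == 1))
})

test_that("empty phantom projects to unit transmission and zero gradients", {
  g <- toyGeom()
  ph <- Phantom(delta = array(0, c(2, 8, 8)), mu = array(0, c(2, 8, 8)),
                voxel_size = samplingPitch(g) * 1e6)
  pr <- projectPhantom(ph, 0.3, wavenumber(g))
  expect_true(all(pr$t == 1))
  expect_true(all(pr$gx == 0) && all(pr$gy == 0))
})

test_that("rendered beamlet displacement follows the refraction relation", {
  ## alpha_x = 1 urad at z_od = 1 m must displace the centroid by
  ## 1 um = 1/2.6 px on a 2.6 um detector
  g <- SetupGeometry(z_od = 1, mean_energy = 16, pixel_size = 2.6,
                     modulator_period = 31.2)
  k <- wavenumber(g)
  one <- matrix(1, 1, 1); zero <- matrix(0, 1, 1)
  alpha <- 1e-6
  fr0 <- renderBeamlets(one, zero, zero, g, flux = Inf)
  fr1 <- renderBeamlets(one, matrix(alpha * k, 1, 1), zero, g, flux = Inf)
  centroid_x <- function(img) sum(col(img) * img) / sum(img)
  shift_px <- centroid_x(intensity(fr1)) - centroid_x(intensity(fr0))
  expect_equal(shift_px, 1 / 2.6, tolerance = 1e-3)
})

test_that("noiseless rendering conserves flux and reproduces the flat", {
  g <- toyGeom()
  nb <- c(4L, 4L)
  zero <- matrix(0, nb[2], nb[1])
  flat <- renderBeamlets(zero + 1, zero, zero, g, flux = Inf)
  same <- renderBeamlets(zero + 1, zero, zero, g, flux = Inf)
  expect_identical(intensity(flat), intensity(same))
  ## sample with t = 0.4 scales each beamlet sum by exactly t
  tmap <- zero + 0.4
  smp <- renderBeamlets(tmap, zero, zero, g, flux = Inf)
  ws <- extractWindow(smp, 2, 2, 12)
  wf <- extractWindow(flat, 2, 2, 12)
  expect_equal(sum(ws) / sum(wf), 0.4, tolerance = 1e-9)
})

test_that("Poisson flat-field statistics match the requested flux", {
  ## wide pitch (24 px) so windows isolate one beamlet's full Gaussian
  g <- SetupGeometry(z_od = 1.28, mean_energy = 16, pixel_size = 2.6,
                     modulator_period = 62.4)
  flux <- 1000
  fl <- simulateFlat(g, c(12L, 12L), flux = flux, seed = 42)
  sums <- vapply(1:12, function(i) vapply(1:12, function(j)
    sum(extractWindow(fl, i, j, 20)), numeric(1)), numeric(12))
  ## 144 beamlets: empirical mean within 3 sigma of the Poisson mean
  expect_lt(abs(mean(sums) - flux), 3 * sqrt(flux / 144) + 0.005 * flux)
  ## determinism: identical seed, identical frame
  fl2 <- simulateFlat(g, c(12L, 12L), flux = flux, seed = 42)
  expect_identical(intensity(fl), intensity(fl2))
  expect_error(renderBeamlets(matrix(1), matrix(0), matrix(0), g,
                              flux = -5), "positive")
})

test_that("scan angles are equally spaced over a half turn", {
  g <- SetupGeometry(z_od = 1, mean_energy = 16, pixel_size = 2.6,
                     modulator_period = 31.2, n_subpitch = 1)
  ph <- Phantom(delta = array(1e-8, c(1, 8, 8)),
                mu = array(10, c(1, 8, 8)),
                voxel_size = samplingPitch(g) * 1e6)
  scan <- simulateScan(ph, g, n_projections = 4, noise = FALSE)
  expect_equal(scan$angles, c(0, 45, 90, 135) * pi / 180)
  expect_length(scan$sample, 4L)
  expect_length(scan$sample[[1]], 1L)
})

test_that("sub-pitch raster offsets tile the period", {
  g <- toyGeom(n_subpitch = 2L)
  ph <- twoMaterialPhantom(g, n = 16L)
  scan <- simulateScan(ph, g, n_projections = 1, noise = FALSE)
  offs <- scan$offsets
  expect_equal(nrow(offs), 4L)
  expect_equal(sort(unique(offs[, 1])), c(0, samplingPitch(g)))
  expect_equal(sort(unique(offs[, 2])), c(0, samplingPitch(g)))
  ## all four (a, b) combinations present
  expect_equal(anyDuplicated(paste(offs[, 1], offs[, 2])), 0L)
})

test_that("a mirror-symmetric phantom projects symmetrically", {
  g <- toyGeom()
  sp <- samplingPitch(g)
  ## centred disc: projection at angle a equals the mirrored projection
  ## at pi - a (parallel-beam symmetry)
  ph <- cylinderPhantom(n = 24, n_slices = 1, voxel_size = sp * 1e6,
                        discs = data.frame(cx = 0, cz = 0, radius = 8,
                                           delta = 1e-7, mu = 300))
  k <- wavenumber(g)
  a <- 30 * pi / 180
  p1 <- projectPhantom(ph, a, k)
  p2 <- projectPhantom(ph, pi - a, k)
  expect_equal(p1$t[1, ], rev(p2$t[1, ]), tolerance = 1e-6)
})
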