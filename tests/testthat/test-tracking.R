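test_that("window extraction is centred on the nominal grid", {
  g <- toyGeom()
  fl <- simulateFlat(g, c(4L, 4L), flux = Inf)
  w <- extractWindow(fl, 2, 3, 12)
  expect_equal(dim(w), c(12L, 12L))
  ## beamlet centred: centroid at the window centre
  cx <- sum(col(w) * w) / sum(w)
  cy <- sum(row(w) * w) / sum(w)
  expect_equal(cx, 6.5, tolerance = 0.1)
  expect_equal(cy, 6.5, tolerance = 0.1)
  ## a window larger than the margin falls off the edge: flagged missing
  expect_null(extractWindow(fl, 1, 1, 200))
  expect_error(extractWindow(fl, 9, 1, 12), "out of grid")
})

test_that("transmission is the windowed intensity ratio", {
  a <- matrix(2, 5, 5)
  expect_equal(transmission(a, a), 1)
  expect_equal(transmission(a * 0.5, a), 0.5)
  ## direct-sum oracle: 8100 / 9000 = 0.9
  s <- matrix(8.1e3 / 25, 5, 5)
  f <- matrix(9.0e3 / 25, 5, 5)
  expect_equal(transmission(s, f), 0.9)
  expect_true(is.na(transmission(a, a * 0)))
})

test_that("subpixel registration recovers imposed shifts", {
  n <- 16
  flat <- gaussSpot(n, 8.5, 8.5)
  ## identical patches
  expect_equal(unname(registerSubpixel(flat, flat, 100)), c(0, 0))
  ## integer shifts are exact (circular)
  m <- gaussSpot(n, 7.5, 9.5)
  ms <- gaussSpot(n, 8.5, 7.5)
  d <- registerSubpixel(ms, m, 1)
  expect_equal(unname(d), c(1, -2))
  ## subpixel shift against the brute-force correlation-scan oracle
  for (sh in list(c(0.30, -0.10), c(-0.42, 0.27))) {
    smp <- gaussSpot(n, 8.5 + sh[1], 8.5 + sh[2])
    d <- registerSubpixel(smp, flat, 100)
    oracle <- bruteForceShift(smp, 8.5, 8.5)
    expect_equal(unname(d), sh, tolerance = 0.011)
    expect_lt(max(abs(d - oracle)), 0.011)
  }
  ## constant patch has no beamlet to track
  expect_true(all(is.na(registerSubpixel(matrix(1, 8, 8),
                                         matrix(1, 8, 8), 10))))
})

test_that("displacements convert to refraction angles through geometry", {
  g <- toyGeom()  # pixel 2.6 um, z_od 1.28 m
  expect_equal(toRefraction(0, 0, g)$alpha_x, 0)
  ## arithmetic oracle: 0.01 px * 2.6 um / 1.28 m = 20.3125 nrad
  expect_equal(toRefraction(0.01, 0, g)$alpha_x, 2.03125e-8)
  ## doubling z_od halves alpha
  g2 <- toyGeom(z_od = 2.56)
  expect_equal(toRefraction(0.01, 0, g2)$alpha_x,
               toRefraction(0.01, 0, g)$alpha_x / 2)
})

test_that("tracking a frame against itself gives unit t and zero shifts", {
  g <- toyGeom()
  fl <- simulateFlat(g, c(4L, 4L), flux = Inf)
  tm <- trackFrame(fl, fl, dark = NULL, geom = g, window = 12,
                   upsampling = 100)
  expect_true(all(transmissionMap(tm) == 1))
  expect_true(all(abs(shiftX(tm)) <= 0.01))
  expect_true(all(abs(shiftY(tm)) <= 0.01))
})

test_that("a dead beamlet is masked and only that one", {
  g <- toyGeom()
  fl <- simulateFlat(g, c(4L, 4L), flux = Inf)
  smp <- fl
  ## zero out the window of beamlet (2, 3)
  img <- intensity(smp)
  xc <- gridOrigin(smp)[1] + 2 * gridPitch(smp)
  yc <- gridOrigin(smp)[2] + 1 * gridPitch(smp)
  rows <- seq(round(yc) - 5, length.out = 12)
  cols <- seq(round(xc) - 5, length.out = 12)
  img[rows, cols] <- 0
  smp@intensity <- img
  tm <- trackFrame(smp, fl, dark = NULL, geom = g, window = 12,
                   upsampling = 10)
  expect_equal(sum(is.na(transmissionMap(tm))), 1L)
  expect_true(is.na(transmissionMap(tm)[2, 3]))
  expect_true(is.na(alphaX(tm)[2, 3]))
})

test_that("tracking recovers simulator ground truth", {
  g <- toyGeom()
  ph <- twoMaterialPhantom(g)
  scan <- simulateScan(ph, g, n_projections = 1, noise = FALSE)
  tm <- trackFrame(scan$sample[[1]][[1]], scan$flats[[1]], dark = NULL,
                   geom = g, window = 12, upsampling = 100)
  n <- nSubpitch(g)
  tru_t <- scan$truth[[1]]$t[seq(1, 2, n), seq(1, 40, n), drop = FALSE]
  tru_ax <- scan$truth[[1]]$gx[seq(1, 2, n), seq(1, 40, n),
                               drop = FALSE] / wavenumber(g)
  expect_lt(sqrt(mean((transmissionMap(tm) - tru_t)^2)), 0.02)
  expect_lt(sqrt(mean((alphaX(tm) - tru_ax)^2)), 0.05 * stats::sd(tru_ax))
})

test_that("retrieval is linear in the imposed refraction angle", {
  ## +/- 5 urad imposed on noiseless beamlets: recovered-vs-imposed
  ## slope within 2% of unity
  g <- toyGeom()
  k <- wavenumber(g)
  alphas <- seq(-5e-6, 5e-6, length.out = 9)
  one <- matrix(1, 1, 3); zero <- matrix(0, 1, 3)
  rec <- vapply(alphas, function(a) {
    fr <- renderBeamlets(one, matrix(a * k, 1, 3), zero, g, flux = Inf)
    fl <- renderBeamlets(one, zero, zero, g, flux = Inf)
    tm <- trackFrame(fr, fl, dark = NULL, geom = g, window = 16,
                     upsampling = 200)
    mean(alphaX(tm))
  }, numeric(1))
  fit <- stats::lm(rec ~ alphas)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.02)
})

test_that("stitching interleaves raster maps and unstitching inverts it", {
  g <- toyGeom(n_subpitch = 2L)
  sp <- samplingPitch(g)
  mk <- function(val, a, b) {
    m <- matrix(val, 2, 2)
    z <- matrix(0, 2, 2)
    new("TrackingMaps", t = m, dx = z, dy = z, alphaX = m * 10,
        alphaY = m * 100, offset = c(a, b) * sp)
  }
  maps <- list(mk(1, 0, 0), mk(2, 1, 0), mk(3, 0, 1), mk(4, 1, 1))
  st <- stitch(maps, g, angle = 0)
  expect_equal(dim(transmissionMap(st)), c(4L, 4L))
  ## declared order: +x offset fills +x output, +y fills +y
  expect_equal(transmissionMap(st)[1, 1:2], c(1, 2))
  expect_equal(transmissionMap(st)[2, 1:2], c(3, 4))
  expect_equal(pitch(st), sp)
  ## round trip
  back <- unstitch(st, g)
  key <- vapply(back, function(m) paste(rasterOffset(m) / sp,
                                        collapse = ","), character(1))
  for (m0 in maps) {
    m1 <- back[[match(paste(rasterOffset(m0) / sp, collapse = ","), key)]]
    expect_equal(transmissionMap(m1), transmissionMap(m0))
    expect_equal(alphaX(m1), alphaX(m0))
  }
  ## duplicate or off-lattice offsets are rejected
  expect_error(stitch(list(mk(1, 0, 0), mk(2, 0, 0), mk(3, 0, 1),
                           mk(4, 1, 1)), g), "duplicate")
  expect_error(stitch(maps[1:3], g), "exactly")
})

test_that("n_subpitch 1 stitching is the identity", {
  g <- toyGeom(n_subpitch = 1L)
  m <- matrix(runif(12) + 0.5, 3, 4)
  z <- matrix(0, 3, 4)
  tm <- new("TrackingMaps", t = m, dx = z, dy = z, alphaX = z, alphaY = z,
            offset = c(0, 0))
  st <- stitch(list(tm), g, angle = 0.1)
  expect_identical(transmissionMap(st), m)
})

test_that("stitched maps match fine-grid ground truth", {
  g <- toyGeom(n_subpitch = 2L)
  ph <- twoMaterialPhantom(g)
  ts <- trackedScan(ph, g, n_projections = 1, noise = FALSE)
  st <- ts$projs[[1]]
  tru <- ts$scan$truth[[1]]
  expect_equal(dim(transmissionMap(st)), dim(tru$t))
  expect_lt(sqrt(mean((transmissionMap(st) - tru$t)^2)), 0.02)
  gx_rec <- alphaX(st) * wavenumber(g)
  expect_lt(stats::sd(gx_rec - tru$gx), 0.05 * stats::sd(tru$gx))
})

test_that("planar-mode scans stitch to the same maps as tomography mode", {
  g <- toyGeom(n_subpitch = 2L)
  ph <- twoMaterialPhantom(g, n = 16L)
  t1 <- trackedScan(ph, g, n_projections = 1, noise = FALSE)
  scan2 <- simulateScan(ph, g, n_projections = 1, noise = FALSE,
                        mode = "planar")
  maps2 <- lapply(seq_along(scan2$flats), function(r)
    trackFrame(scan2$sample[[1]][[r]], scan2$flats[[r]], dark = NULL,
               geom = g, window = 12, upsampling = 100))
  st2 <- stitch(maps2, g, angle = 0)
  expect_equal(transmissionMap(st2), transmissionMap(t1$projs[[1]]),
               tolerance = 1e-6)
})

test_that("grid localization recovers the simulated lattice", {
  g <- toyGeom()
  fl <- simulateFlat(g, c(6L, 5L), flux = 5e4, seed = 3)
  grid <- locateGrid(intensity(fl), approx_pitch = 12)
  expect_equal(grid$pitch, gridPitch(fl), tolerance = 0.02)
  expect_equal(grid$dim, c(6L, 5L))
  expect_equal(grid$origin[1], gridOrigin(fl)[1], tolerance = 0.6)
  expect_equal(grid$origin[2], gridOrigin(fl)[2], tolerance = 0.6)
})
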