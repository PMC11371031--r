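test_that("angular sensitivity reduces to the two-window formulas", {
  ## constant map: zero sigma
  m <- matrix(5e-8, 20, 20)
  est <- angularSensitivity(m, list(c(1, 1, 5, 5), c(10, 10, 5, 5)))
  expect_equal(sigmaMean(est), 0)
  ## two windows with known stds s1, s2: mean (s1+s2)/2, SEM |s1-s2|/2
  set.seed(9)
  m2 <- matrix(0, 10, 40)
  m2[1:5, 1:20] <- stats::rnorm(100, sd = 1)
  m2[6:10, 21:40] <- stats::rnorm(100, sd = 3)
  w <- list(c(1, 1, 5, 20), c(6, 21, 5, 20))
  s1 <- stats::sd(m2[1:5, 1:20]); s2 <- stats::sd(m2[6:10, 21:40])
  est2 <- angularSensitivity(m2, w)
  expect_equal(sigmaMean(est2), (s1 + s2) / 2)
  expect_equal(sigmaSem(est2), abs(s1 - s2) / 2)
  ## a window containing masked values is excluded with a warning
  m2[2, 2] <- NA
  expect_warning(
    est3 <- angularSensitivity(m2, c(w, list(c(1, 21, 5, 20)))),
    "excluded")
  expect_equal(est3@nWindows, 2L)
  expect_error(angularSensitivity(m2, list(c(1, 1, 50, 50),
                                           c(1, 1, 2, 2))), "outside")
})

test_that("sensitivity estimates an i.i.d. Gaussian angle noise level", {
  set.seed(31)
  sigma <- 30e-9
  m <- matrix(stats::rnorm(64 * 64, sd = sigma), 64, 64)
  est <- angularSensitivity(m, tileWindows(c(64, 64), n = 8,
                                           shape = c(8, 8)))
  expect_lt(abs(sigmaMean(est) - sigma), 3 * sigmaSem(est) + 0.02 * sigma)
})

test_that("sensitivity estimator is unbiased on Gaussian maps", {
  set.seed(77)
  sigma <- 1
  wins <- tileWindows(c(24, 24), n = 4, shape = c(6, 6))
  ests <- replicate(400, {
    m <- matrix(stats::rnorm(24 * 24, sd = sigma), 24, 24)
    sigmaMean(angularSensitivity(m, wins))
  })
  ## small-sample sd bias for n = 36 is ~0.7%; allow it plus MC error
  mc_sem <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - sigma), 0.01 * sigma + 3 * mc_sem)
})

test_that("visibility spans its limits", {
  ## perfect on/off checker of period 4: visibility 1
  img <- matrix(0, 32, 32)
  img[(row(img) - 1) %% 4 < 2 & (col(img) - 1) %% 4 < 2] <- 10
  expect_equal(visibility(img, pitch_px = 4), 1)
  ## constant frame: 0
  expect_equal(visibility(matrix(3, 16, 16), pitch_px = 4), 0)
  ## Gaussian beamlets on the simulated pitch: matches the analytic
  ## folded-profile value
  g <- toyGeom()
  fl <- simulateFlat(g, c(8L, 8L), flux = Inf)
  v <- visibility(fl)
  p <- gridPitch(fl)
  ## analytic unit cell of a periodic Gaussian array, sigma = 2 px
  xs <- seq(-0.5, 0.5, length.out = 201) * p
  cell <- outer(xs, xs, function(x, y) {
    s <- 0
    for (ix in -2:2) for (iy in -2:2)
      s <- s + exp(-((x - ix * p)^2 + (y - iy * p)^2) / (2 * 4))
    s
  })
  q <- stats::quantile(cell, c(0.01, 0.99), names = FALSE)
  v_ref <- (q[2] - q[1]) / (q[2] + q[1])
  expect_equal(v, v_ref, tolerance = 0.05)
})

test_that("power-law fits recover exact exponents", {
  x <- c(1, 2, 4, 8)
  f1 <- fitPowerLaw(x, 1 / x)
  expect_equal(f1$exponent, -1, tolerance = 1e-12)
  f2 <- fitPowerLaw(x, 3 * x^-0.5)
  expect_equal(f2$exponent, -0.5, tolerance = 1e-12)
  expect_equal(f2$prefactor, 3, tolerance = 1e-12)
  expect_error(fitPowerLaw(c(1, 2), c(1, 2)), "three")
  expect_error(fitPowerLaw(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("FRC of identical images is one and symmetric in its arguments", {
  set.seed(5)
  img <- matrix(stats::rnorm(64 * 64), 64, 64)
  c1 <- frc(img, img, pitch = 6.25e-6)
  v <- frcValues(c1)
  expect_true(all(abs(v[is.finite(v)] - 1) < 1e-9))
  expect_true(is.na(crossingFreq(c1)))
  expect_true(is.na(resolution(c1)))
  ## symmetry
  other <- img + matrix(stats::rnorm(64 * 64), 64, 64)
  cab <- frc(img, other)
  cba <- frc(other, img)
  expect_equal(frcValues(cab), frcValues(cba))
  expect_error(frc(img, img[1:32, 1:32]), "shape")
})

test_that("the 3-sigma threshold follows the ring population", {
  set.seed(6)
  c1 <- frc(matrix(stats::rnorm(64 * 64), 64, 64),
            matrix(stats::rnorm(64 * 64), 64, 64))
  thr <- frcThreshold(c1)
  npix <- c1@nPix
  expect_equal(thr, 3 / sqrt(npix / 2))
  ## the threshold decreases monotonically with ring population
  ord <- order(npix[-1])
  expect_true(all(diff(thr[-1][ord]) <= 0))
})

test_that("pure-noise images decorrelate at nearly all rings", {
  set.seed(8)
  c1 <- frc(matrix(stats::rnorm(128 * 128), 128, 128),
            matrix(stats::rnorm(128 * 128), 128, 128))
  v <- frcValues(c1)[-1]; thr <- frcThreshold(c1)[-1]
  expect_gt(mean(v < thr, na.rm = TRUE), 0.9)
  expect_lt(mean(v, na.rm = TRUE), 0.15)
})

test_that("a shared band-limited signal crosses near its cutoff", {
  set.seed(10)
  n <- 128; cutoff <- 0.25
  fr <- 0:(n - 1); fr[fr > n / 2] <- fr[fr > n / 2] - n
  rad <- sqrt(outer(fr^2, fr^2, "+")) / n
  Fsig <- matrix(complex(real = stats::rnorm(n * n),
                         imaginary = stats::rnorm(n * n)), n, n)
  sig <- Re(stats::fft(Fsig * (rad <= cutoff), inverse = TRUE)) / (n * n)
  sig <- sig / stats::sd(sig)
  i1 <- sig + 0.1 * matrix(stats::rnorm(n * n), n, n)
  i2 <- sig + 0.1 * matrix(stats::rnorm(n * n), n, n)
  c1 <- frc(i1, i2, pitch = 6.25e-6)
  expect_equal(crossingFreq(c1), cutoff, tolerance = 0.08)
  expect_equal(resolution(c1), 6.25e-6 / crossingFreq(c1))
})

test_that("slice-averaged FRC averages curves and reduces variance", {
  set.seed(12)
  n <- 48; ny <- 6
  mkvol <- function() {
    a <- array(stats::rnorm(ny * n * n), c(ny, n, n))
    new("Volume", voxels = a, voxelSize = 6.25e-6, channel = "mu")
  }
  base <- array(rep(stats::rnorm(n * n), each = ny), c(ny, n, n))
  v1 <- mkvol(); v1@voxels <- base + 0.3 * v1@voxels
  v2 <- mkvol(); v2@voxels <- base + 0.3 * v2@voxels
  avg <- frcAveraged(v1, v2, slice_indices = 1:5)
  single <- frc(matrix(v1@voxels[1, , ], n, n),
                matrix(v2@voxels[1, , ], n, n))
  ## identical slice pairs: averaging changes nothing
  same <- v1
  rep1 <- array(rep(v1@voxels[1, , ], each = ny), c(ny, n, n))
  same@voxels <- rep1
  same2 <- v2
  same2@voxels <- array(rep(v2@voxels[1, , ], each = ny), c(ny, n, n))
  avg_same <- frcAveraged(same, same2, slice_indices = 1:5)
  expect_equal(frcValues(avg_same), frcValues(single), tolerance = 1e-9)
  ## averaging reduces ring-to-ring scatter about the smooth trend
  rough <- function(v) stats::sd(diff(v[3:20]))
  expect_lt(rough(frcValues(avg)), rough(frcValues(single)))
  expect_error(frcAveraged(v1, v2, slice_indices = 1:4), "five")
  expect_error(frcAveraged(v1, v2, slice_indices = c(1, 3, 4, 5, 6)),
               "adjacent")
})

test_that("threshold crossings convert to real-space resolution", {
  expect_equal(crossingToResolution(0.4, 6.25e-6), 15.625e-6)
  expect_equal(round(crossingToResolution(0.4, 6.25e-6) * 1e6), 16)
  expect_equal(crossingToResolution(0.5, 1e-5), 2e-5)
  expect_equal(crossingToResolution(0.25, 1e-5), 4e-5)
  ## no crossing: sampling-limited, no finite resolution to report
  expect_true(is.na(crossingToResolution(NA, 6.25e-6)))
  expect_error(crossingToResolution(0.7, 6.25e-6), "0.5")
})

test_that("empty-beam sigma is deterministic given a seed", {
  g <- toyGeom(z_od = 0.4)
  s1 <- emptyBeamSigma(g, grid_dim = c(6L, 6L), flux = 1000, seed = 5)
  s2 <- emptyBeamSigma(g, grid_dim = c(6L, 6L), flux = 1000, seed = 5)
  expect_identical(s1, s2)
  expect_gt(s1, 0)
})
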