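anchorBorder <- function(m) {
  n <- nrow(m); c <- ncol(m)
  bg <- matrix(FALSE, n, c)
  bg[c(1, n), ] <- TRUE; bg[, c(1, c)] <- TRUE
  m - mean(m[bg])
}

test_that("refraction angles scale to phase gradients by the wavenumber", {
  k <- energyToWavenumber(16)
  z <- matrix(0, 3, 3)
  expect_identical(gradientsFromRefraction(z, z, k)$gx, z)
  a <- matrix(1e-6, 2, 2)
  g <- gradientsFromRefraction(a, z[1:2, 1:2], k)
  expect_equal(g$gx[1, 1], 8.10837e4, tolerance = 1e-5)
  expect_equal(gradientsFromRefraction(a, a, 2 * k)$gx, 2 * g$gx)
})

test_that("zero gradients integrate to a zero phase map", {
  z <- matrix(0, 32, 32)
  pm <- integrateFourier(z, z, 6.25e-6)
  expect_true(all(phaseShift(pm) == 0))
})

test_that("integration recovers an analytic sinusoid", {
  n <- 256; pitch <- 6.25e-6; L <- 64; A <- 3
  X <- col(matrix(0, n, n))
  phi <- A * sin(2 * pi * X / L)
  gx <- (2 * pi * A / L) * cos(2 * pi * X / L) / pitch
  pm <- integrateFourier(gx, matrix(0, n, n), pitch)
  expect_lt(sqrt(mean((phaseShift(pm) - anchorBorder(phi))^2)), 1e-3 * A)
})

test_that("integration recovers a Gaussian bump from its finite differences", {
  n <- 256; pitch <- 6.25e-6; s <- 20
  X <- col(matrix(0, n, n)); Y <- row(matrix(0, n, n))
  phi <- exp(-((X - n / 2)^2 + (Y - n / 2)^2) / (2 * s^2))
  gx <- matrix(0, n, n); gy <- matrix(0, n, n)
  gx[, 2:(n - 1)] <- (phi[, 3:n] - phi[, 1:(n - 2)]) / (2 * pitch)
  gy[2:(n - 1), ] <- (phi[3:n, ] - phi[1:(n - 2), ]) / (2 * pitch)
  pm <- integrateFourier(gx, gy, pitch)
  err <- abs(phaseShift(pm) - anchorBorder(phi))
  expect_lt(max(err[9:(n - 8), 9:(n - 8)]), 0.01)
})

test_that("a constant x-gradient integrates to the exact linear ramp", {
  pitch <- 2e-6
  gc <- matrix(7, 24, 24)
  pm <- integrateFourier(gc, matrix(0, 24, 24), pitch)
  slopes <- diff(t(phaseShift(pm))) / pitch
  expect_equal(range(slopes), c(7, 7), tolerance = 1e-9)
  ## adding a constant to gx adds a ramp: difference of two integrals
  gx0 <- matrix(rnorm(24 * 24, sd = 0.5), 24, 24)
  p0 <- phaseShift(integrateFourier(gx0, matrix(0, 24, 24), pitch))
  p1 <- phaseShift(integrateFourier(gx0 + 7, matrix(0, 24, 24), pitch))
  d <- p1 - p0
  ramp_slopes <- diff(t(d)) / pitch
  expect_equal(mean(ramp_slopes), 7, tolerance = 1e-6)
  expect_lt(stats::sd(ramp_slopes), 1e-6)
})

test_that("integration then differentiation returns the curl-free input", {
  set.seed(1)
  n <- 64; pitch <- 1e-6
  ## band-limited random phase field
  f <- stats::fft(matrix(stats::rnorm(n * n), n, n))
  fr <- 0:(n - 1); fr[fr > n / 2] <- fr[fr > n / 2] - n
  att <- exp(-(outer(fr^2, fr^2, "+")) / 6)
  phi <- Re(stats::fft(f * att, inverse = TRUE)) / (n * n)
  grad <- function(m) {
    gx <- matrix(0, n, n); gy <- matrix(0, n, n)
    gx[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / (2 * pitch)
    gx[, 1] <- (m[, 2] - m[, 1]) / pitch
    gx[, n] <- (m[, n] - m[, n - 1]) / pitch
    gy[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * pitch)
    gy[1, ] <- (m[2, ] - m[1, ]) / pitch
    gy[n, ] <- (m[n, ] - m[n - 1, ]) / pitch
    list(gx = gx, gy = gy)
  }
  g <- grad(phi)
  rec <- phaseShift(integrateFourier(g$gx, g$gy, pitch))
  gb <- grad(rec)
  i <- 5:(n - 4)
  expect_lt(stats::sd((gb$gx - g$gx)[i, i]), 0.05 * stats::sd(g$gx[i, i]))
  expect_lt(stats::sd((gb$gy - g$gy)[i, i]), 0.05 * stats::sd(g$gy[i, i]))
})

test_that("the anchored phase is gauge-invariant and the flip flag flips", {
  n <- 48; pitch <- 1e-6
  X <- col(matrix(0, n, n))
  gx <- cos(2 * pi * X / 16)
  gy <- matrix(0, n, n)
  p1 <- phaseShift(integrateFourier(gx, gy, pitch))
  p2 <- phaseShift(integrateFourier(gx, gy, pitch, sign_flip = TRUE))
  expect_equal(p2, -p1)
  ## anchoring: declared background region has mean zero
  bg <- matrix(FALSE, n, n); bg[, 1:4] <- TRUE
  p3 <- phaseShift(integrateFourier(gx, gy, pitch, background = bg))
  expect_equal(mean(p3[bg]), 0, tolerance = 1e-12)
})

test_that("projection integration matches simulator ground-truth phase", {
  g <- toyGeom(n_subpitch = 2L)
  ph <- twoMaterialPhantom(g)
  ts <- trackedScan(ph, g, n_projections = 2, noise = FALSE)
  k <- wavenumber(g)
  pm <- integrateProjection(ts$projs[[1]], k)
  tru <- ts$scan$truth[[1]]$dphi
  tru <- tru - mean(tru[, c(1, 2, 39, 40)])
  expect_lt(sqrt(mean((phaseShift(pm) - tru)^2)),
            0.05 * max(abs(tru)))
})
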