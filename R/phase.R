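## Fourier-space integration of the two orthogonal refraction (phase
## gradient) maps into a single phase-shift map: the complex gradient
## field gx + i gy is divided by 2 pi i (u + i v) in Fourier space, which
## inverts the derivative for any curl-free field in one step.

#' Refraction angles to phase gradients
#'
#' The transverse gradient of the phase shift is k times the refraction
#' angle per axis.
#'
#' @param alpha_x,alpha_y refraction-angle maps (rad), same shape
#' @param k vacuum wavenumber (1/m)
#' @return list with `gx`, `gy` (rad/m)
#' @export
gradientsFromRefraction <- function(alpha_x, alpha_y, k) {
  stopifnot(identical(dim(alpha_x), dim(alpha_y)))
  list(gx = k * alpha_x, gy = k * alpha_y)
}

## Mirror-pad one gradient component along columns (x). Mirroring the
## phase field makes it even under reflection, so its x-gradient must be
## continued antisymmetrically in x (parity -1) while the y-gradient is
## continued symmetrically (parity +1), and vice versa along rows. A bare
## antisymmetric mirror leaves a jump of twice the border gradient at the
## seam, which rings back into the map; a cubic-Hermite apron of 2*w
## samples that matches value and slope on both sides removes it.
.pad_cols <- function(m, parity, w) {
  nc <- ncol(m)
  gR <- m[, nc]; gL <- m[, 1L]
  sR <- if (nc >= 2L) m[, nc] - m[, nc - 1L] else gR * 0
  sL <- if (nc >= 2L) m[, 2L] - m[, 1L] else gL * 0
  herm <- function(v0, s0, v1, s1, len) {
    tt <- (1:len) / (len + 1)
    outer(v0, 2 * tt^3 - 3 * tt^2 + 1) +
      outer(s0 * (len + 1), tt^3 - 2 * tt^2 + tt) +
      outer(v1, -2 * tt^3 + 3 * tt^2) +
      outer(s1 * (len + 1), tt^3 - tt^2)
  }
  capR <- herm(gR, sR, parity * gR, -parity * sR, 2L * w)
  capL <- herm(parity * gL, -parity * sL, gL, sL, 2L * w)
  cbind(m, capR, parity * m[, rev(seq_len(nc)), drop = FALSE], capL)
}

.pad_rows <- function(m, parity, w) t(.pad_cols(t(m), parity, w))

## Signed FFT frequency coordinates in cycles per metre for n samples of
## spacing h.
.fftfreq <- function(n, h) {
  f <- 0:(n - 1)
  f[f > n / 2] <- f[f > n / 2] - n
  f / (n * h)
}

#' Integrate two orthogonal gradient maps into a phase map
#'
#' Fourier-space integration: with F the 2D Fourier transform and (u, v)
#' the spatial-frequency coordinates in cycles/m,
#' `dphi = Re( Finv( F(gx + i gy) / (2 pi i (u + i v)) ) )`.
#' The DC term, which the method cannot recover, is set to zero and the
#' result is re-anchored to mean zero over a background region. The mean
#' gradient (whose integral is an exact linear ramp) is handled
#' analytically; the residual gradient maps are mirror-padded to about
#' twice their size with slope-matched seams before the transform to
#' suppress wrap-around leakage on non-periodic fields, then cropped.
#'
#' @param gx,gy phase-gradient maps (rad/m), x along columns, y along rows
#' @param pitch lateral sampling pitch (m)
#' @param background logical matrix marking the anchor region (mean phase
#'   forced to zero there); NULL uses the one-pixel border ring
#' @param angle rotation angle to record (rad)
#' @param sign_flip flip the global sign of the output (convention flag)
#' @param apron half-width (px) of the slope-matched seam blend in the
#'   mirror padding
#' @return a [PhaseMap-class]
#' @export
integrateFourier <- function(gx, gy, pitch, background = NULL,
                             angle = NA_real_, sign_flip = FALSE,
                             apron = 8L) {
  stopifnot(identical(dim(gx), dim(gy)), pitch > 0)
  nr0 <- nrow(gx); nc0 <- ncol(gx)
  ## a constant gradient integrates to an exact ramp; take it out first
  ## so the padded residual is DC-free
  g0x <- mean(gx); g0y <- mean(gy)
  w <- as.integer(apron)
  gxp <- .pad_rows(.pad_cols(gx - g0x, -1, w), 1, w)
  gyp <- .pad_rows(.pad_cols(gy - g0y, 1, w), -1, w)
  nr <- nrow(gxp); nc <- ncol(gxp)
  u <- .fftfreq(nc, pitch)   # x frequencies, along columns
  v <- .fftfreq(nr, pitch)   # y frequencies, along rows
  U <- matrix(u, nr, nc, byrow = TRUE)
  V <- matrix(v, nr, nc)
  den <- 2i * pi * (U + 1i * V)
  G <- stats::fft(gxp + 1i * gyp)
  integ <- G / den
  integ[1L, 1L] <- 0
  phi <- Re(stats::fft(integ, inverse = TRUE)) / (nr * nc)
  phi <- phi[seq_len(nr0), seq_len(nc0), drop = FALSE]
  phi <- phi + pitch * (g0x * (col(phi) - 1) + g0y * (row(phi) - 1))
  if (is.null(background)) {
    background <- matrix(FALSE, nr0, nc0)
    background[c(1L, nr0), ] <- TRUE
    background[, c(1L, nc0)] <- TRUE
  }
  stopifnot(identical(dim(background), dim(phi)), any(background))
  phi <- phi - mean(phi[background])
  if (sign_flip) phi <- -phi
  new("PhaseMap", dphi = phi, pitch = pitch, angle = as.numeric(angle))
}

#' Integrate the refraction maps of a stitched projection
#'
#' Convenience wrapper chaining [gradientsFromRefraction()] and
#' [integrateFourier()] for a [StitchedProjection-class]. Masked (NA)
#' refraction values are replaced by zero gradient before integration.
#' The default anchor region is the outermost columns on both sides of
#' the projection (air to the left and right of a sample narrower than
#' the field of view), which makes the phase maps consistent line
#' integrals (zero in air) across all rotation angles.
#'
#' @param proj a [StitchedProjection-class]
#' @param k vacuum wavenumber (1/m)
#' @param background anchor region (see [integrateFourier()]); NULL uses
#'   edge columns of width `max(1, ncol/16)` per side
#' @return a [PhaseMap-class]
#' @export
integrateProjection <- function(proj, k, background = NULL) {
  stopifnot(is(proj, "StitchedProjection"))
  g <- gradientsFromRefraction(alphaX(proj), alphaY(proj), k)
  g$gx[!is.finite(g$gx)] <- 0
  g$gy[!is.finite(g$gy)] <- 0
  if (is.null(background)) {
    d <- dim(g$gx)
    w <- max(1L, d[2L] %/% 16L)
    background <- matrix(FALSE, d[1L], d[2L])
    background[, c(seq_len(w), d[2L] - seq_len(w) + 1L)] <- TRUE
  }
  integrateFourier(g$gx, g$gy, pitch(proj), background = background,
                   angle = projAngle(proj))
}
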