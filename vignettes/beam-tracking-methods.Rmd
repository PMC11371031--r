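---
title: "Beam-tracking phase-contrast imaging: models, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-tracking phase-contrast imaging: models, parameters and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(BeamTrack)
```

This vignette is the package's account of the science it implements:
the forward model behind the synthetic data, the retrieval chain, the
numerical choices made where the method leaves room, and what the test
suite does and does not demonstrate.

## The measurement model

A two-directional beam-tracking set-up structures the beam with an
amplitude modulator of period $p$ into a grid of beamlets, each resolved
by the detector as a bright spot. Under a geometrical-optics,
small-angle approximation a thin sample changes each beamlet in two
independent ways:

* **Attenuation.** The spot's integrated intensity scales by the
  transmission $t = \exp(-\int \mu\, \mathrm{d}l)$.
* **Refraction.** The spot's centre moves on the detector by
  $\Delta x = z_\mathrm{od}\,\alpha_x$ (and likewise in $y$), where
  $\alpha_{x} = \frac{1}{k}\,\partial_x \Delta\Phi$ is the refraction
  angle, $\Delta\Phi = -k \int \delta\, \mathrm{d}l$ the phase shift,
  and $k = 2\pi E / hc$ the vacuum wavenumber ($hc$ fixed at
  1.23984198 keV·nm).

Both relations are linear in the line integrals of $\mu$ and $\delta$,
which is what makes the retrieved images tomographically consistent:
$-\log t$ and $-\Delta\Phi / k$ are parallel-beam sinogram entries and
can be reconstructed by filtered back projection into $\mu$ (1/m) and
$\delta$ (dimensionless) volumes.

Assumptions inherited from this model, and kept throughout the package:
geometrical optics (no Fresnel fringes — the regime in which propagation
distances stay within roughly a metre), a single effective energy for
the (in reality pink) beam, parallel-beam geometry (source hundreds of
metres away), and refraction small enough that a beamlet stays inside
its analysis window.

All internal lengths are metres and angles radians; micrometres appear
only in constructors and file metadata. This prevents the silent
$10^x$ mistakes that mixed detector-µm / distance-cm bookkeeping
invites.

## The synthetic acquisition generator

`simulateScan()` is a first-class part of the package, not a test
helper: it produces flat, dark and sample frames from a voxelized
phantom under exactly the model above, so every downstream stage can be
checked against ground truth.

* Phantoms are voxel grids of $\delta$ and $\mu$, indexed `[y, x, z]`
  with y the rotation axis. Voxels are *point samples* of the fields,
  interpolated bilinearly along rays; a uniform slab of $n$ voxels
  therefore integrates over $n-1$ pitches between its outer voxel
  centres. `cylinderPhantom()` builds extruded discs and can band-limit
  the interfaces (`edge_sigma`, voxels) so the object is resolvable at
  the sampling pitch — the right property for a calibration object.
* Projections are computed by resampling rays at each angle (the volume
  is never rotated, avoiding double interpolation when comparing to the
  same routine used as oracle). Phase gradients are central differences
  of the projected $\Delta\Phi$ on the fine grid.
* Each beamlet is rendered as an isotropic Gaussian spot, default
  $\sigma = 2$ px (FWHM $\approx$ 4.7 px, i.e. about 12 µm on a 2.6 µm
  detector — close to a 15 µm aperture). The spot is displaced by
  $z_\mathrm{od}\,\alpha / \text{pixel}$ and scaled by the local $t$;
  Poisson noise is drawn per pixel at the requested flux
  (photons/beamlet), on top of a dark background (default 100 counts,
  Gaussian read noise $\sigma = 2$).
* The sub-pitch raster moves the modulator in tomography mode (the grid
  shifts on the detector, the sample stays put, one flat per raster
  position) and the sample in planar mode; both record the offset in
  the same convention so stitching is identical.

What the generator does **not** emulate: beamlet broadening
(ultra-small-angle scattering / dark field), source-size or scintillator
blur, spectral effects and beam hardening, detector distortion. Tests
passing on synthetic data show that the *retrieval chain is faithful to
the stated model*, not that the model captures every property of real
beamline frames. In particular the simulator makes no claim to
reproduce measured visibility figures, which depend on unmodelled
blur; the beamlet width is the single knob.

## Retrieval choices

**Windows.** Each beamlet is analysed in a `window × window` patch
centred on its *nominal* lattice position (the window does not follow
the refracted spot, and is flagged missing rather than clipped at the
frame edge). The window should match the beamlet pitch on the detector:
neighbouring spots' tails inside an oversized window pull the
correlation peak toward their displacements and shrink recovered
gradients by several percent. The test geometry uses a 12 px window on
a 12 px pitch; set-ups with a 50 µm period on 2.6 µm pixels
(pitch 19.23 px) would use the conventional 20 px window, with the
marginal overlap accepted.

**Registration.** `registerSubpixel()` implements single-step upsampled
cross-correlation: integer-pixel peak from the FFT cross-correlation,
then a matrix-multiply DFT evaluates the correlation on a
$1/\text{upsampling}$-pixel grid in a ±1.5 px neighbourhood. Default
upsampling 100 → quantum 0.01 px, i.e. 26 nm at 2.6 µm pixels or
about 20 nrad at $z_\mathrm{od} = 1.28$ m — matching the sensitivity
scale of interest. The real part of the correlation is maximized
(patches are real); a constant patch has no peak and flags the beamlet
invalid.

**Flats and darks.** The dark frame is subtracted from sample and flat
frames (clipped at zero) before analysis; one flat per modulator raster
position is used, with no temporal interpolation.

**Stitching.** With $n$ sub-pitch steps per axis, output pixel
$(i n + b,\; j n + a)$ takes beamlet $(i, j)$ of the map acquired at
raster slot $(a, b)$, so increasing modulator offset along $+x$ fills
increasing output $x$. Offsets must form the complete $n \times n$
lattice; duplicates or gaps are errors, not warnings. `unstitch()` is
the exact inverse permutation.

## Phase integration

`integrateFourier()` solves $\nabla \Phi = (g_x, g_y)$ in one step by
dividing the Fourier transform of $g_x + i g_y$ by
$2\pi i (u + i v)$, which inverts the derivative for any curl-free
field. Numerical decisions:

* **DC term.** The method cannot recover the mean; the DC coefficient is
  zeroed and the result re-anchored to mean zero over a declared
  background region (default for projections: air strips at the lateral
  edges, width `ncol/16` per side; for standalone maps: the one-pixel
  border ring).
* **Mean gradient.** A constant gradient integrates to an exact ramp;
  it is removed before the transform and its ramp added back
  analytically, so tilted fields are handled without leakage.
* **Padding.** Non-periodic fields leak badly through the periodic FFT.
  Each gradient map is mirror-continued with the correct parity (the
  $x$-gradient of a mirrored field is odd under the $x$-mirror, the
  $y$-gradient even, and vice versa). A bare mirror still leaves a jump
  of twice the border gradient at the seam; a cubic-Hermite apron
  (default 8 px half-width) matching value and slope on both sides of
  each seam removes it. On 256² oracles this brings the sinusoid
  recovery error down to the $10^{-6}$ scale and the Gaussian-bump
  error to machine-level — the suite asserts the coarser bounds
  (RMS $< 10^{-3}$ of amplitude).
* Masked refraction values enter the integration as zero gradient; all-
  zero gradients produce the zero map.

Because each projection's anchor is estimated from finitely many noisy
background pixels, integrated maps carry a small random offset per
projection. `phaseSinogram(..., air_cols = )` optionally re-zeroes each
sinogram row on declared air columns (standard air normalization);
without it those offsets accumulate into low-frequency artefacts of the
$\delta$ reconstruction.

## Tomography

Sinograms are $-\log t$ (masked or non-positive transmission bins
inpainted by 1D linear interpolation along the detector row — the ramp
filter does not tolerate NaN) and $-\Delta\Phi / k$. Reconstruction is
slice-by-slice parallel-beam FBP with the discrete Ram-Lak kernel
($h(0) = 1/4\Delta^2$, $h(n) = -1/\pi^2 n^2 \Delta^2$ for odd $n$, zero
for even $n$), applied by FFT convolution with zero padding to the next
power of two above $2N$, and linear-interpolation back projection with
the centre of rotation fixed at $(N+1)/2$. The reconstruction grid
equals the stitched-projection grid; no upsampling, no ring correction,
no centre-of-rotation auto-calibration. The discrete kernel (rather
than a sampled $|\nu|$ ramp) is what keeps the interior of a uniform
disc accurate to better than a percent, which the suite checks against
closed-form chord-length sinograms.

`splitHalfDatasets()` assigns alternating projections to two halves
that keep their true angles — the standard construction of independent
inputs for Fourier ring correlation.

## Characterization metrics

* **Angular sensitivity** is the mean, over several declared sample-free
  windows, of the per-window standard deviation of the refraction-angle
  map, with the spread across windows as its standard error. Window
  shape is free (conventional choices: 5 × 40 px in planar studies,
  8 × 8 in tomography configurations); windows containing masked pixels
  are excluded with a warning.
* **Scaling laws.** On simulated empty-beam frames the angle noise
  scales as $1/z_\mathrm{od}$ (the displacement noise on the detector is
  independent of distance) and as $N^{-1/2}$ in the number of averaged
  frames while photon noise dominates. `emptyBeamSigma()` +
  `fitPowerLaw()` (log–log least squares) recover both exponents; the
  reference flat is noiseless so the sweep isolates the sample-frame
  photon noise.
* **Visibility** folds the flat frame by the beamlet period into one
  average unit cell and uses robust 1st/99th-percentile extrema in
  $(I_\max - I_\min)/(I_\max + I_\min)$.
* **FRC.** Rings one Fourier pixel wide;
  $\mathrm{FRC}(r) = |\sum_r F_1 F_2^*| / \sqrt{\sum_r |F_1|^2 \sum_r |F_2|^2}$;
  threshold $3/\sqrt{N(r)/2}$ (the 3σ criterion). The innermost rings
  hold so few pixels that the threshold exceeds 1, so the outward
  crossing scan starts at the first ring where the curve is above the
  threshold; the first fall below it, linearly interpolated between
  rings, gives the crossing, and resolution = pitch / crossing. A curve
  that never falls below the threshold is reported as sampling-limited
  rather than assigned a number. For volumes, the FRC of five adjacent
  middle slices is averaged ring-by-ring before thresholding.

## Study conditions used by the test suite

The simulated studies run at desk scale, with sizes chosen so the whole
suite and the acceptance script each complete in well under a minute:

* toy geometry: 31.2 µm period on 2.6 µm pixels (12 px pitch),
  $z_\mathrm{od}$ 0.1–1.28 m, 16 keV;
* sensitivity sweeps: 12 × 12 beamlet grids at 1000 photons/beamlet,
  distances {0.1, 0.2, 0.4, 0.8} m, frame counts {1, 2, 4, 8, 16};
* end-to-end tomography: a 40-voxel two-material cylinder (soft matrix
  $\delta = 2\times10^{-7}$, $\mu = 1500$/m; inclusion
  $\delta = 4\times10^{-7}$, $\mu = 3000$/m; interfaces band-limited to
  one voxel), 60 angles, 2 × 2 raster, 2 × 10⁵ photons/beamlet.
  The flux puts the edge-signal-to-noise ratio near 30, the regime a
  high-sensitivity synchrotron set-up operates in (tens of nrad noise
  against µrad-scale tissue refraction); at much lower flux the 5%
  recovery check would measure the low-frequency noise of the
  integrated-phase channel rather than the pipeline's accuracy, which
  is what it is meant to verify.

Region means are taken on eroded masks (3 px inside interfaces) so they
test reconstruction values, not edge rendering.

## Known limitations

* Single effective energy; no spectral weighting of the pink beam.
* No dark-field (beamlet-broadening) channel.
* The geometrical-optics model degrades beyond ~1 m propagation or for
  refraction approaching the beamlet pitch; neither regime is simulated.
* Fourier integration assumes air (or at least a usable anchor region)
  somewhere in the field of view; fields entirely filled by sample
  would keep an unknown offset per projection.
* FBP assumes equally spaced angles over [0°, 180°) and a centred
  rotation axis; the centre offset is not auto-calibrated.
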