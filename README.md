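# BeamTrack

Two-directional beam-tracking (2DBT) X-ray phase-contrast imaging and
tomography in R.

In a 2DBT set-up a high-Z amplitude modulator (a grid of small apertures
with period *p*) structures a synchrotron beam into an array of
independent beamlets that a high-resolution detector resolves
individually. A sample placed downstream changes each beamlet in two
ways:

- its **intensity** drops by the transmission
  `t = exp(-∫ μ dl)`, the line integral of the linear attenuation
  coefficient μ;
- its **position** shifts by `Δx = z_od · α`, where the refraction angle
  `α = (1/k) ∇ΔΦ` is the transverse gradient of the phase shift
  `ΔΦ = -k ∫ δ dl`, with δ the refractive-index decrement and `k = 2πE/hc`
  the wavenumber.

Tracking every beamlet therefore yields, per frame, a transmission map
and two orthogonal refraction-angle maps. Raster-scanning the modulator
in sub-pitch steps and interleaving ("stitching") the per-beamlet maps
gives images sampled at `p / n_subpitch`, finer than the apertures
themselves. The two gradients are integrated in Fourier space into ΔΦ,
and filtered back projection over rotation angles reconstructs voxel
maps of μ and δ — attenuation and phase tomograms of the same scan.

The package is aimed at people developing or characterizing such
set-ups: every stage is exposed as a testable function, and a synthetic
acquisition generator (geometrical-optics forward model with Poisson
noise) provides ground truth for all of them.

## What is inside

| Stage | Functions |
| --- | --- |
| Geometry and unit plumbing | `SetupGeometry()`, `energyToWavenumber()`, `samplingPitch()`, `scanExposure()`, `readGeometry()` |
| Synthetic acquisitions | `Phantom()`, `cylinderPhantom()`, `projectPhantom()`, `renderBeamlets()`, `simulateScan()`, `simulateFlat()`, `simulateDark()` |
| Beamlet retrieval | `extractWindow()`, `transmission()`, `registerSubpixel()` (upsampled cross-correlation), `toRefraction()`, `trackFrame()`, `stitch()`, `locateGrid()` |
| Phase integration | `gradientsFromRefraction()`, `integrateFourier()` (Fourier-space integration of both gradients), `integrateProjection()` |
| Tomography | `attenuationSinogram()`, `phaseSinogram()`, `fbpReconstruct()` (Ram-Lak FBP), `splitHalfDatasets()` |
| Characterization | `angularSensitivity()`, `emptyBeamSigma()`, `visibility()`, `fitPowerLaw()`, `frc()`, `frcAveraged()`, `crossingToResolution()` |
| Pipeline / IO | `runPipeline()`, TIFF+JSON readers and writers, `inst/cli/beamtrack.R` |

## Worked example

Simulate a tomographic scan of a two-material cylinder (a soft matrix
with a denser inclusion), retrieve it, and reconstruct both channels:

```r
library(BeamTrack)

geom <- SetupGeometry(z_od = 1.28, mean_energy = 16, pixel_size = 2.6,
                      modulator_period = 31.2, n_subpitch = 2)
ph <- cylinderPhantom(n = 40, n_slices = 2,
                      voxel_size = samplingPitch(geom) * 1e6,
                      discs = data.frame(cx = c(0, 4), cz = c(0, 3),
                                         radius = c(14, 5.5),
                                         delta = c(2e-7, 4e-7),
                                         mu = c(1500, 3000)),
                      edge_sigma = 1)
scan <- simulateScan(ph, geom, n_projections = 60, flux = 2e5, seed = 1)

projs <- lapply(seq_along(scan$angles), function(ia) {
  maps <- lapply(seq_along(scan$flats), function(r)
    trackFrame(scan$sample[[ia]][[r]], scan$flats[[r]], dark = scan$dark,
               geom = geom, window = 12, upsampling = 100))
  stitch(maps, geom, angle = scan$angles[ia])
})

k <- wavenumber(geom)
phases <- lapply(projs, integrateProjection, k = k)
vol_mu <- fbpReconstruct(attenuationSinogram(projs), "mu")
vol_de <- fbpReconstruct(phaseSinogram(phases, k, air_cols = c(1:3, 38:40)),
                         "delta")
```

Printing the intermediate objects shows the pipeline state, e.g.

```
StitchedProjection: 2 x 40 px at 15.6 um, angle 0 deg
PhaseMap: 2 x 40 px at 15.6 um, range [-9.761, 0.21] rad
Volume (delta): 2 x 40 x 40 voxels at 15.6 um
```

and comparing region means of the reconstructions against the phantom:

```
mu    (matrix / inclusion): 1496 / 2991 per m   (truth 1500 / 3000)
delta (matrix / inclusion): 2.01e-07 / 3.98e-07 (truth 2e-07 / 4e-07)
```

both channels come back within about 1% under these conditions. The
resolution of a reconstruction is estimated the standard way — two
independent half-dataset reconstructions compared by Fourier ring
correlation against a 3σ noise threshold:

```r
halves <- splitHalfDatasets(projs)
v1 <- fbpReconstruct(attenuationSinogram(halves$first), "mu")
v2 <- fbpReconstruct(attenuationSinogram(halves$second), "mu")
frc(matrix(voxels(v1)[1, , ], 40, 40), matrix(voxels(v2)[1, , ], 40, 40),
    pitch = samplingPitch(geom))
#> FRCCurve: 21 rings
#>   3-sigma crossing at 0.309 cycles/px -> 50.4 um
```

A curve that never falls below the threshold is reported as
sampling-limited (resolution at least as good as the sampling pitch).

## Command line

```sh
Rscript inst/cli/beamtrack.R run --config config.yaml --out out_dir
```

Subcommands `simulate`, `track`, `integrate`, `reconstruct`, `frc`,
`sensitivity`, `run`. Stages are idempotent and resumable: each writes a
done-marker with provenance (config hash, seed, package version), and
re-running skips completed stages. Exit codes: 0 success, 2 config
error, 3 data error.

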