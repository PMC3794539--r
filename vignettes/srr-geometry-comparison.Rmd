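---
title: "Comparing acquisition geometries for super-resolution reconstruction of multislice MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing acquisition geometries for super-resolution reconstruction of multislice MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

2D multislice MRI of small animals is routinely acquired with in-plane
voxels 5-10 times finer than the slice thickness, because thin slices cost
signal-to-noise and acquisition time that in vivo imaging cannot afford.
The resulting anisotropic voxels suffer partial-volume averaging along the
slice-select axis: reformatted views look blurry and through-plane
structure is lost. Super-resolution reconstruction (SRR) recovers an
isotropic high-resolution (HR) volume from several low-resolution (LR)
multislice stacks acquired from different viewpoints of the same field of
view. Three stack-geometry families are in use:

* **shifted** — the same stack repeated with subvoxel translations along
  the slice axis; N = slice thickness / in-plane spacing stacks tile one
  slice thickness;
* **rotational** — the slice-select direction rotated in equal increments
  (default six views, 30 degrees apart; views beyond a half rotation
  duplicate planes);
* **orthogonal** — three stacks with mutually orthogonal slice axes
  (axial, coronal, sagittal).

`srrgeom` implements the whole comparison as a simulation study: digital
phantoms stand in for scanned ones, a multislice forward model generates
the LR stacks, an Irani-Peleg iterative back-projection (IBP) core
reconstructs the HR volume, and a metric suite (SNR, CNR, sigmoid
edge-width fitting, tube-modulation depth, acquisition-time accounting)
quantifies the trade-offs per geometry and voxel aspect ratio (AR, the
1:1:N of the LR voxel).

## Forward model

An LR stack is simulated from an HR volume in four steps
(`simulate_lr_stack()`):

1. **Transform** into the stack frame (`transform_volume()`). Orthogonal
   geometries are exact axis permutations; shifts resample along the
   slice axis; rotations resample bilinearly in the x-z plane about the
   volume center (the rotation axis is the volume's y axis, so the
   slice-select direction sweeps x-z). The slice-select direction is
   always the third array axis of the stack frame.
2. **Blur** along the slice axis only, with a 1D Gaussian whose FWHM
   equals the slice thickness — a close model of a multislice excitation
   profile. The kernel is truncated at three standard deviations (under
   0.3% mass) and renormalized to unit sum, so constants pass through
   exactly; near the volume edge the truncated kernel is renormalized
   again rather than padded.
3. **Decimate** by point-sampling the blurred volume at slice centers,
   spaced one slice thickness apart with the first slice centered in its
   slab. The blur carries the entire partial-volume effect, so no slab
   averaging is stacked on top of it. In-plane resolution is left at the
   HR grid spacing: only the slice axis is degraded, as in the
   acquisitions this emulates.
4. **Noise**: additive Gaussian by default (simple moments, so tests have
   closed-form oracles); Rician (magnitude of complex Gaussian) is
   available because magnitude MR images are Rician — but note the
   background-ROI noise estimate used by SNR is then biased by the
   Rayleigh floor.

`upsample_stack()` inverts the decimation approximately: linear
interpolation between slice centers along the slice axis only, clamped to
the nearest slice beyond the terminal centers so no signal is fabricated
outside the acquired field of view.

## Reconstruction

`ibp_reconstruct()` is plain Irani-Peleg iterative back-projection:

* the initial estimate is the voxelwise mean of all stacks, upsampled and
  inverse-transformed to the world frame (`ibp_initialize()`);
* each iteration simulates the LR acquisitions from the current estimate
  with the same forward model at zero noise (`ibp_simulate()`), measures
  the residual e(i) — the maximum over stacks of a per-stack norm of
  observed minus simulated (`ibp_residual()`, `max_abs` by default, `rms`
  available) — and back-projects the mean upsampled difference with no
  damping (`ibp_update()`);
* iteration stops when e(i) falls below a preset threshold or at the
  iteration cap.

Support is tracked per stack: a voxel outside a stack's
inverse-transformed support (rotational stacks do not cover the corners
of the world grid) is excluded from that stack's contribution and the 1/N
weighting adapts per voxel; voxels covered by no stack take a declared
fill intensity. Out-of-support resampling uses the scene's background
intensity rather than zero, so dark rinds are not painted into background
ROIs.

### Stopping, and why the experiment uses a fixed budget

The residual threshold defaults to 1e-3 of the input dynamic range with a
cap of 20 iterations: noise-free fixtures converge well below the
threshold, and the AR 1 case drives the residual under 1e-6 of the
dynamic range (verified in the tests).

With noisy stacks the residual stalls at the noise floor and the
threshold is never reached, so the cap is what stops the loop — and the
choice matters. Undamped IBP run long enough converges toward exact data
consistency, which means fitting the noise of every stack into the HR
estimate: measured per-iteration curves on the biological phantom show
edge restoration saturating within roughly three to five iterations while
background noise keeps growing, until every SRR variant has *worse* SNR
than single-stack interpolation. `run_comparison()` therefore runs a
fixed budget of 4 IBP updates in every cell. A fixed budget also keeps
the optimization treatment identical across geometries, which an adaptive
stop does not: residual floors differ by geometry, so a shared threshold
would compare a twice-iterated shifted reconstruction against a
six-times-iterated orthogonal one. Both the budget and the threshold are
configurable.

## Synthetic phantoms

Real reference data for this kind of study are scanner acquisitions; the
package replaces them with two fully controlled digital phantoms. Both
render object membership on a 3x3x3 subvoxel grid per voxel and average,
approximating the scanner's intrinsic partial-volume effect — hard binary
masks alias and contaminate edge-width measurements.

**Resolution phantom** (`make_resolution_phantom()`): five parallel
cylinders of 0.7 mm outer diameter separated by 0.7 mm wall-to-wall,
rendered as signal voids (sealed tube wall plus trapped air) in a bright
homogeneous bath, on a 26 mm field of view at 128^3 by default. The tube
*row* runs along the default slice-select axis, so slabs thicker than the
gap cannot separate the tubes — the configuration whose through-plane
resolution the phantom probes. The oblique variant tilts the tube long
axis by 40 degrees in the x-y plane and 55 degrees in the y-z plane; the
row is then kept as close to the slice axis as rigidity allows (the
component of z orthogonal to the tilted axis, which retains a 0.78
projection on the slice axis). Whether the physical mount kept rows even
closer to the slice axis is not recoverable, and matters: the residual
in-plane separation is exactly what lets a single interpolated stack
weakly resolve the oblique tubes in this simulation (see Limitations).
Because the tube walls and lumen are both void in the data this emulates,
the full outer diameter is rendered void; the wall/lumen distinction is
not separable.

**Biological phantom** (`make_biological_phantom()`): nested smoothed
ellipsoids rather than an atlas, for full control of region homogeneity
and edge sharpness — a dark surround (susceptibility-matched bath
analogue, intensity 5), a body ellipsoid ("tissue", 90), an inner liver
ellipsoid (55), and three bright rods three voxels across (fine-structure
analogue, 100), on a 6.4 mm field of view at 128^3 (0.05 mm isotropic) by
default. The generator also *places the measurements*: four 9x9x9 voxel
box ROIs (signal and CNR-high in tissue, CNR-low in the liver, noise in
pure background within every geometry's support) and twenty
boundary-normal line segments crossing the liver boundary at
spherical-Fibonacci directions, all recomputed from the construction so
they remain valid when the seed jitters ellipsoid centers and semi-axes
by a few percent to make replicates anatomically distinct. Grids below 96
voxels per axis are refused: the design is scale-relative and the
background noise ROI would no longer clear the body.

The noise default in `experiment_config()` is sigma 4 against tissue at
~90-100, giving LR stacks an SNR in the low twenties — the range typical
of the small-animal acquisitions emulated here.

## Metrics

* `compute_snr()`: mean(signal ROI) / sd(background ROI).
* `compute_cnr()`: |mean(high) - mean(low)| / max(sd(high), sd(low)).
* `fit_sigmoid_edge()`: Levenberg-Marquardt fit of
  f(x) = a1 + a2 / (1 + exp(-a3 (x - a4))) to a boundary profile,
  initialized from the data (baseline = min, amplitude = range, location
  = half-range crossing, slope from the 10-90% crossing distance).
  Descending profiles are flipped so a3 > 0. The edge width is 4.4 / a3
  HR pixels; the exact 10-90% rise of the logistic is 2 ln 9 = 4.394 per
  unit slope, so the conventional 4.4 agrees to two significant figures
  and a3 = 4.4 means a one-voxel rise. Profiles are supersampled at 0.25
  HR pixel to stabilize fits on sharp edges. Fits that fail, place the
  edge outside the profile, or imply a width longer than the profile are
  flagged and *dropped* from means, never imputed; `mean_edge_width()`
  reports how many of its (default 20) profiles converged.
* `tube_modulation()`: resolvability score for the resolution phantom —
  local minima of the run-length-compressed profile, kept only when their
  depth below the lower flanking maximum reaches 10% of the profile's
  dynamic range (so noise wiggles do not count as tubes); fewer than
  n_tubes qualifying minima scores 0 (unresolved), otherwise the mean
  relative depth of the n_tubes deepest minima.

## Numerical conventions

* Axis order (x, y, z), 1-based indices, column-major arrays (x fastest,
  matching NIfTI); voxel centers at origin + (index - 1) * spacing; the
  default origin centers the grid on the physical origin.
* Rotations about the volume's geometric center; out-of-support fill is
  the declared background.
* Volumes round-trip through NIfTI-1 with spacing in `pixdim` and origin
  in the sform.
* Per-cell seeds derive from the master seed by a fixed counter over
  (geometry, AR, replicate, stack), so any cell can be re-run alone and
  a whole report is bit-reproducible.

## A worked comparison

```{r}
library(srrgeom)
cfg <- experiment_config(aspect_ratios = c(4, 6), n_replicates = 5,
                         master_seed = 1)
report <- run_comparison(cfg)
summarize_report(report)
autoplot(report)
```

Problem sizes used throughout the package's own experiments: 128^3 HR
grids (0.05 mm biological, 0.203 mm resolution phantom), ARs 4-6, five
replicates, four IBP updates per cell — chosen as the smallest setting at
which the geometry effects are well clear of the replicate scatter.

## What the simulation does and does not show

The simulated comparison reproduces several findings of phantom studies
of acquisition geometry:

* all three SRR geometries sharpen boundaries well beyond single-stack
  interpolation at every AR tested, and resolve the aligned tube phantom
  that interpolation cannot;
* on the oblique tube phantom, orthogonal and rotational reconstructions
  recover the five tubes far better than shifted stacks, whose single
  slice axis must deconvolve the entire through-plane structure;
* orthogonal acquisition needs the fewest stacks, hence the least
  acquisition time (3 stacks vs 4-6 shifted and 6 rotational at equal
  per-stack time).

One published trend does **not** emerge under matched per-stack noise,
and the package reports this honestly rather than engineering it in: the
SNR ordering orthogonal > rotational > shifted inverts here. Orthogonal
acquisition averages only three stacks (least noise averaging) and its
residual decays fastest (fastest noise fitting), so it retains the most
background noise at any iteration count, while rotational averages six
obliquely-resampled (hence smoothed) stacks. Real-scanner orderings
plausibly reflect acquisition-side effects this model excludes — coil and
readout orientation, and the registration resampling that scanner stacks
undergo before reconstruction. Two further clauses are statistical ties
at the study conditions rather than robust effects: the
orthogonal-versus-rotational mean edge width (the two differ by a few
hundredths of a pixel, with the sign depending on the seed), and the
oblique interpolated baseline's resolvability (its noiseless profile
retains weak minima because rigidity caps the tube row's
slice-axis projection at the stated tilt angles; under acquisition noise
the prominence rule scores it unresolved).

Passing tests therefore demonstrate internal consistency of the forward
model, reconstruction, and metrics, and the geometry effects that survive
the idealizations — not that real-scanner SNR tables are reproduced.

## Known limitations

* No physical MR signal model: relaxation, flip angle, coil sensitivity
  and k-space effects are out of scope; noise is additive per stack.
* Stacks are generated in known frames; registration of genuinely
  misaligned data is not addressed.
* Arbitrary oblique slice orientations are not supported — geometries are
  axis-anchored and the *phantom* is orientable.
* Only the Irani-Peleg optimizer is implemented; regularized
  least-squares variants are deliberately absent.
* Intensities are assumed comparable across stacks; real multi-series
  data would need intensity normalization before the residual is
  meaningful.
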