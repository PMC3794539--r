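# srrgeom

Super-resolution reconstruction (SRR) of 2D multislice MRI, and a
simulation framework for comparing the three acquisition-geometry
families used to drive it.

## The problem

Small-animal MRI at isotropic high resolution takes hours; in vivo
imaging therefore uses 2D multislice acquisitions whose in-plane voxels
are 5–10× finer than the slice thickness (voxel aspect ratio, AR, of
1:1:4 to 1:1:10). The thick slices partial-volume-average anatomy along
the slice-select axis. SRR recovers an isotropic high-resolution (HR)
volume from several low-resolution (LR) stacks of the same field of view
acquired from different viewpoints:

* **shifted** — N = AR copies of the stack, subvoxel-translated along the
  slice axis so the shifts tile one slice thickness;
* **rotational** — six views with the slice-select direction rotated in
  30° increments (a half rotation; beyond it, planes duplicate);
* **orthogonal** — three views with mutually orthogonal slice axes.

Which family buys the most image quality per minute of scanner time is an
experimental question. `srrgeom` implements the whole comparison in
silico, for imaging scientists planning such acquisitions and for testing
SRR implementations: digital phantoms (a five-tube resolution phantom and
an embryo-like nested-ellipsoid phantom that places its own measurement
ROIs and edge profiles), a multislice forward model, the reconstruction
core, and the quality metrics.

## The method

The forward model of one LR stack from an HR volume `G` is

    f_k = D S_h T_k G + noise,

where `T_k` is the stack's geometric transform (shift, rotation, or axis
permutation), `S_h` convolves along the slice-select axis with a 1D
Gaussian slice profile of FWHM equal to the slice thickness, and `D`
point-samples the blurred volume at slice centers (decimation by the AR).
Reconstruction is Irani–Peleg iterative back-projection (IBP): starting
from the mean of the upsampled, inverse-transformed stacks,

    G(i+1) = G(i) + (1/N) Σ_k T_k⁻¹ U (f_k − D S_h T_k G(i)),

with `U` linear upsampling along the slice axis, iterated until the
residual `e(i) = max_k ‖f_k − f̂_k(i)‖` drops below a preset threshold or
an iteration cap. Image quality is scored by SNR (mean signal over
background noise sd), CNR (|S_h − S_l| / max(σ_h, σ_l)), and edge width
from sigmoid fits `f = a1 + a2 / (1 + exp(−a3(x − a4)))` across tissue
boundaries, where width = 4.4 / a3 HR pixels (the 10–90% rise length of
the logistic, 2 ln 9 ≈ 4.39 per unit slope); tube resolvability on the
resolution phantom is scored as the relative modulation depth across the
five tube minima.

## Worked example

```r
library(srrgeom)

cfg <- experiment_config(aspect_ratios = c(4, 6), n_replicates = 5,
                         master_seed = 1)
report <- run_comparison(cfg)
summarize_report(report)
```

Averaged over the five replicates, the AR 1:1:4 rows of the summary read
(values from this exact call):

| geometry     | stacks | minutes | SNR  | CNR | edge width (px) |
|--------------|-------:|--------:|-----:|----:|----------------:|
| isotropic    |      1 |    18.5 | 22.9 |  8.5 |            1.32 |
| interpolated |      1 |     3   | 27.6 | 10.7 |            3.63 |
| shifted      |      4 |    12   | 29.9 | 11.3 |            2.21 |
| rotational   |      6 |    18   | 24.3 |  9.3 |            1.80 |
| orthogonal   |      3 |     9   | 17.6 |  6.6 |            1.76 |

Reading it: every SRR geometry roughly halves the boundary width of the
single-stack interpolated baseline (3.63 px) toward the isotropic
reference (1.32 px), with orthogonal acquisition getting there in the
least scanner time (9 min vs 12–18). In this matched-noise simulation the
SNR ranking runs shifted > rotational > orthogonal — more stacks means
more noise averaging — which is the opposite of what scanner studies
report for real acquisitions; the methods vignette
(`vignettes/srr-geometry-comparison.Rmd`) discusses why, and what the
idealized noise model leaves out.

On the oblique five-tube resolution phantom at AR 1:1:5, the tube
modulation scores from the same pipeline are orthogonal 0.82 and
rotational 0.88 (tubes cleanly resolved), shifted 0.56 (resolved but
blurred), interpolated baseline 0.00 (unresolved).

Individual stages are exposed directly: `make_resolution_phantom()`,
`make_biological_phantom()`, `plan_shifted()` / `plan_rotational()` /
`plan_orthogonal()`, `simulate_lr_stack()`, `ibp_reconstruct()` (with
`tidy()` / `glance()` / `autoplot()` on the fit), `compute_snr()`,
`compute_cnr()`, `fit_sigmoid_edge()`, `mean_edge_width()`,
`tube_modulation()`, and NIfTI I/O via `read_volume()` /
`write_volume()`. A thin command-line wrapper for the full comparison
lives at `inst/cli/srr-compare.R`.

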