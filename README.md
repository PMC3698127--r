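# sparsect

Sparse-view micro-CT reconstruction and vascular quantification in R.

In vivo micro-CT can cut X-ray dose and scan time proportionally by
acquiring fewer projection views — at the price of angular-undersampling
streaks that can ruin the downstream vessel segmentation. `sparsect`
implements the full computational chain needed to study that trade-off on
a synthetic, analytically known vascular phantom:

* **Geometry & projectors** — circular-trajectory fan-beam (2D) and
  cone-beam (3D) geometries; a pixel-driven forward projector and a
  voxel-driven back projector (compiled, deliberately unmatched, mirroring
  GPU practice), plus a dense system-matrix oracle built from the same
  sampling loop for exact verification and matched-pair experiments;
  retrospective view subsampling (`subsample_views()`).
* **Reconstruction** — the multiplicative image space reconstruction
  algorithm (ISRA)

  $$x_j^{k+1} = x_j^k\,\frac{[A^T m]_j}{[A^T A x^k]_j},$$

  nonnegativity-preserving, with the measured sinogram back-projected once
  and cached; its one-step-late total-variation variant (ISRA-TV), which
  adds $\lambda\,s\,\partial U/\partial x_j(x^k)$ to the denominator, where
  $U$ is a smoothed isotropic TV energy and $s$ a sensitivity scale that
  makes $\lambda$ (default 0.001) transferable across geometries; both stop
  at 0.14% relative change between iterates. A ramp-filtered fan-beam FBP
  / Feldkamp FDK baseline.
* **Phantom** — an arch-shaped 1.2 mm vessel with analytic centerline and
  exact voxel mask in a soft-tissue body with a bone insert; Beer–Lambert
  projection simulation with Poisson photon noise.
* **Segmentation** — the semi-automatic chain: VOI statistics, ±3σ
  threshold, 26-neighbourhood erosion, seeded region growing, dilation,
  hole filling.
* **Evaluation** — TP/FP/FN voxel classification, distance-transform
  centerline extraction, orthogonal-plane best-fit diameters, mean
  centerline distance, Student's t-tests across subjects, and a driver
  (`run_experiment()`) reproducing the full algorithm × view-level matrix
  with provenance records.

## Worked example

```r
library(sparsect)

ph   <- make_vessel_phantom(seed = 1)              # 192^2 grid, 1.2 mm vessel
geom <- scan_geometry(n_views = 512, det_pitch = 0.35, det_count = 200)
proj <- simulate_projections(ph, geom, photons = 1e4, seed = 2)

rec <- isra_tv(subsample_views(proj, 4),           # 128-view, 1/4-dose scan
               vol_template = ph$attenuation)
rec
#> <ct_recon> isra_tv, 63 iterations (converged)
#>   lambda = 0.001 (sensitivity scale 22.89), tv_delta = 1.4e-06
#>   final stop metric 0.1371% (threshold 0.14%)
#>   3014 negative sinogram entries clipped to 0

mask <- segment_vessels(rec$volume, phantom_seed_voi(ph))
classify_voxels(mask, ph$vessel_mask)
#> <classification> TP 1738 (0.872), FP 0 (0.000), FN 256 (0.128) of 1994 reference voxels

cl <- extract_centerline(mask)
cl
#> <centerline> 75 control points, length 15 mm, diameter 1.04 +/- 0.068 mm
centerline_distance(cl, ph$centerline)             # mm, sub-voxel
#> [1] 0.03800439
```

The classification line says 87% of the true vessel voxels were recovered
with zero spurious voxels at a quarter of the views; the centerline of the
segmented vessel lies 0.04 mm (less than half a voxel) from the analytic
truth, and the mean lumen diameter is recovered to within ~0.16 mm of the
true 1.2 mm (the ±3σ threshold excludes partial-volume edge voxels, so
masks slightly underestimate).

A command-line wrapper with `phantom`, `recon`, `segment`, `evaluate` and
`run-all` subcommands is installed at `inst/cli/sparsect.R`.

## The vignette

`vignettes/sparse-view-vascular-ct.Rmd` documents the model and its
assumptions: the projector conventions, the TV discretization and the
one-step-late penalty scaling (including its calibration and failure
modes), the stopping rule, what the phantom does and does not emulate, the
segmentation protocol's documented ambiguities, and the centerline
replacement for the proprietary reference tool.
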