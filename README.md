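# nuclei3d

Direct extraction of nuclei centroids from 3D fluorescence microscopy
stacks — without segmentation.

## The problem

Tracking cell nuclei through early embryonic development requires finding
the centre of every nucleus in each 3D confocal stack. Segmentation-based
pipelines struggle exactly where embryo images are hardest: juxtaposed and
dividing cells, low contrast, non-uniform background. `nuclei3d` instead
detects centroids *directly*, as stable local maxima of a multiscale,
locally enhanced intensity field, and is aimed at workflows processing
stacks of a few hundred voxels per side holding tens of bright,
quasi-spherical nuclei (largest diameter `D_max ≈ 30` voxels on a
near-isotropic grid).

## The method

Given a raw stack `I` with voxel spacing `(Δx, Δy, Δz)`:

1. **Pre-processing.** A separable truncated Gaussian with per-axis
   half-lengths `h_r = max(1, ⌈σ/Δ_r⌉)` (σ = 0.77 µm gives a 5×5×3 kernel
   at 0.385×0.385×3 µm) suppresses high-frequency noise, followed by a
   3×3×3 median filter against impulsive noise; cubic spline interpolation
   along z then produces near-isotropic voxels (28 slices at 3 µm become
   224 at 0.375 µm). Variant-2 additionally restricts all later processing
   to candidate regions: a global Otsu mask retains nucleus-like voxels,
   yielding a *hybrid image* that is zero elsewhere.
2. **Local enhancement.** Cube-mean filters of odd lengths
   `ℓ_s = odd(f_s · D_max)`, `f_s ∈ {0.3, 0.5, 0.7}`, are applied
   separably (x, then y, then z); the locally enhanced image is the
   voxelwise optimum `LEI(x) = max_s (I * cube_ℓs)(x)`, so every voxel
   carries the response of the best-matching nucleus size.
3. **Centroid extraction.**
   - *Stage 1 — characteristic ratio.* At every voxel with `LEI > 0`, the
     ratio `R` = fraction of the 7×7×7 neighbourhood (centre included)
     with intensity ≤ the centre. Voxels with `R ≥ T_R = 0.97` form
     clusters; each 26-connected cluster contributes one candidate at its
     coordinate mean. An ideal peak has `R = 1`.
   - *Stage 2 — profile shape.* Along each axis, an intensity profile of
     length `N_p = odd(0.7 · D_max)` centred on the candidate is reduced
     to slope labels (+1/0/−1); the score
     `S = 2·min(n⁺_left, n⁻_right)/(N_p − 1)` is 1 only for symmetric
     convex profiles and 0 for flat or linear ones. Candidates with mean
     axis score `S_f < T_S = 0.85` are discarded.
   - *Stage 3 — fragment merging.* Surviving centroids closer than
     `T_D = 0.5 · D_max = 15` voxels are grouped by transitive closure and
     replaced by their coordinate mean, combining intra-nuclear fragments.
4. **Evaluation.** Estimates are matched one-to-one to ground truth inside
   a closed 10-voxel window (closest first); sensitivity `100·TP/N_GT`,
   precision `100·TP/N_est`, RMSE over matched distances, and voxel-level
   specificity `100·TN/(TN+FP)` with `TN = voxels − N_GT − FP`.

A seeded synthetic-embryo generator (`synthetic_spec()` /
`generate_embryo()`) emits phantoms with known centroids — Gaussian-falloff
nuclei, interior fragments, touching pairs, background gradient, Gaussian
and impulse noise — so the whole pipeline is testable without microscope
data.

## Worked example

```r
library(nuclei3d)

spec <- synthetic_spec(shape = c(128, 128, 128), n_nuclei = 17,
                       touching_pairs = 0, seed = 7)
phantom <- generate_embryo(spec)

det <- run_pipeline(phantom$volume)
#> multiscale filtering at lengths 9, 15, 21
#> stage counts: 90 -> 17 -> 17
glance(det)
#> # A tibble: 1 × 4
#>   variant n_stage1 n_stage2 n_stage3
#>     <int>    <int>    <int>    <int>
#> 1       1       90       17       17

m <- match_centroids(phantom$centroids, tidy(det), radius = 10)
detection_metrics(m, phantom$centroids, tidy(det),
                  volume_shape = dim(phantom$volume))
#> # A tibble: 1 × 9
#>      tp    fp    fn  n_gt n_est sensitivity precision  rmse specificity
#>   <int> <int> <int> <int> <int>       <dbl>     <dbl> <dbl>       <dbl>
#> 1    17     0     0    17    17         100       100 0.165         100
```

Stage 1 found 90 raw maxima clusters (mostly weak background domes),
profile-shape screening cut them to the 17 real nuclei, and no fragments
needed merging; every ground-truth centroid was recovered within the
10-voxel window with a positional RMSE of 0.165 voxels.

`autoplot(det)` plots the detected centroids; `plot_slice(vol, z, centroids)`
overlays them on a slice. A command-line interface with `run`, `eval`,
`synth` and `dmax` subcommands ships at
`system.file("cli", "nuclei3d", package = "nuclei3d")`.

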