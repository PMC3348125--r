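---
title: "Direct 3D nuclei-centroid detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct 3D nuclei-centroid detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuclei3d)
```

## The model and its assumptions

`nuclei3d` treats a fluorescently labelled nucleus as a bright,
quasi-spherical blob whose intensity decreases gradually from the centre
to the boundary. Under that assumption a nucleus centre is a *stable local
maximum* of a suitably smoothed intensity field, and centroids can be read
off directly — no segmentation, and therefore no sensitivity to
segmentation failure on touching or dividing cells. The method further
assumes:

- nucleus diameters span a known range, summarized by the largest diameter
  `D_max` (voxels, near-isotropic grid); all length-like parameters are
  tied to it;
- the background varies slowly compared to a nucleus diameter (a global
  threshold can isolate candidate regions; a linear-gradient background
  does not create convex profile shapes at the Stage-2 scale);
- noise is a mixture of high-frequency (Gaussian-filterable) and impulsive
  (median-filterable) components.

The pipeline is `smooth → interpolate → [mask] → enhance → three extraction
stages`; each stage only ever *removes or merges* candidates, so the
per-stage counts are non-increasing — a property the test suite asserts on
every generated volume.

## Coordinates and containers

Volumes are `nuc_volume` objects: a 3D array indexed `[x, y, z]` (z = slice
axis) plus per-axis spacing in µm. All coordinates are **1-based fractional
voxel indices** on the near-isotropic grid — the natural convention for R
arrays; every distance-valued parameter (matching radius 10, `T_D` = 15) is
translation-invariant, so only the bounds convention `[1, n]` depends on
this choice. Centroid sets are plain tibbles (`label`, `x`, `y`, `z`,
`score`), so results chain directly into dplyr/ggplot2; fitted objects
support `tidy()`, `glance()` and `autoplot()`.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `preprocess.sigma_phys` | 0.77 | µm | Gaussian scale; half-lengths `h_r = max(1, ⌈σ/Δ_r⌉)` give 5×5×3 at 0.385×0.385×3 µm |
| `preprocess.median_size` | 3 | voxels | cubic median window against impulse noise |
| `interp.factor` | auto | — | z upsampling; `round(Δz/Δx)` when the grid is anisotropic (8 for 3 → 0.375 µm) |
| `msf.dmax` | 30 | voxels | largest nucleus diameter; anchors every scale below |
| `msf.fractions` | 0.3, 0.5, 0.7 | — | cube-filter lengths as fractions of `D_max` → 9, 15, 21 |
| `stage1.neighborhood` | 7 | voxels | characteristic-ratio cube edge; large enough to see one nucleus, never two |
| `stage1.ratio_threshold` | 0.97 | — | `T_R`; an ideal peak scores 1.0, noise lowers attainable ratios |
| `stage2.profile_fraction` | 0.70 | — | profile length `N_p = odd(0.7 · D_max)` = 21 |
| `stage2.shape_threshold` | 0.85 | — | `T_S`; below `T_R` because real nuclei are imperfectly symmetric |
| `stage2.combine` | mean | — | axis-score combination; `min` is a stricter alternative |
| `stage3.distance_threshold` | `0.5·D_max` = 15 | voxels | `T_D`; fragment search length ≈ nucleus radius |
| `eval.radius` | 10 | voxels | closed matching window around each GT centroid |

`estimate_dmax()` automates the `D_max` measurement on the lowest
time-point volume: Otsu binarization, 26-connected components, rejection of
components with digital sphericity `ψ = π^(1/3)(6V)^(2/3)/A < 0.6`, then
the equivalent-sphere diameter `(6V/π)^(1/3)` of the largest survivor. The
cutoff 0.6 reflects the digital-surface bias: face counting overestimates a
sphere's area by ≈ 1.5×, so digitized balls plateau near ψ ≈ 2/3 while
sheets and filaments fall well below.

## Numerical choices

- **Gaussian kernel sizing.** The half-length rule `h_r = ⌈σ/Δ_r⌉`
  (clamped to ≥ 1) is anchored to its printed consequence — a 5×5×3 kernel
  at the raw confocal resolution — and the kernel is a truncated,
  renormalized Gaussian evaluated at physical offsets `i·Δ_r`, so the
  smoothing is isotropic in µm even on the anisotropic raw grid. Smoothing
  runs *before* z-interpolation.
- **Cubic z-interpolation** uses `stats::spline` (`method = "fmm"`), which
  reproduces polynomials up to degree 3 exactly; output intensities are
  clamped to the input range so the spline cannot overshoot at sharp
  transitions, and positions past the last input slice replicate it.
- **Borders** are edge-replicate for every convolution and the median;
  the characteristic-ratio neighbourhood is instead *clipped* (counts run
  over in-bounds voxels only), so the ratio stays a well-defined fraction
  at faces and corners.
- **Otsu** maximizes between-class variance over a 256-bin histogram of
  the linearly rescaled intensity range; the first maximizing cut wins.
  A constant volume has no threshold and raises a *degenerate input*
  condition (CLI exit code 3) rather than an arbitrary answer.
- **Shape score.** The slope-label statistic
  `S = 2·min(n⁺_left, n⁻_right)/(N_p − 1)` is the simplest score meeting
  all the stated constraints: 1.0 iff every left slope rises and every
  right slope falls; 0 for flat and for monotone (linear) profiles; graded
  decay with asymmetry or roughness. Axis scores combine by arithmetic
  mean (default), tolerating mild single-axis asymmetry at `T_S = 0.85`.
- **Boundary profiles** are clipped symmetrically (both half-lengths
  shrink together) but scored against the *nominal* `N_p`: a slope that
  cannot be observed counts as non-supporting. Without this, a candidate
  on a volume face is judged by as few as two slopes and a gentle noise
  dome trivially scores 1.0 — Stage 2 exists precisely to remove such
  boundary over-detections. An axis with no symmetric window at all
  contributes 0.
- **Stage-3 merging** is the transitive closure of `d_ij ≤ T_D`,
  implemented with a disjoint-set forest, so the grouping is independent
  of input order (a greedy pass would not be); it is checked against a
  brute-force boolean-closure oracle. Group centroids are unweighted
  coordinate means.
- **Matching** accepts candidate pairs in ascending distance order
  (ties broken by label for determinism), guaranteeing one-to-one pairing
  even when 10-voxel windows overlap; the window is a closed ball, so a
  distance of exactly 10 matches and 11 does not.

## The synthetic generator

`synthetic_spec()` defaults describe the study conditions the package
targets: a 261×261×224 near-isotropic grid holding 17 nuclei of radius
8–15 voxels (`D_max ≈ 30`), peak intensity 200 over a background of 20
with a linear gradient of amplitude 0.15 × peak along a random direction,
Gaussian noise with sd 8, impulse noise on 10⁻⁴ of the voxels (half set to
0, half to 2 × peak), one interior fragment per nucleus (amplitude
0.15 × peak, radius r/4, offset < r/3), a minimum centre gap of 32 voxels
and one touching pair placed at a centre gap equal to the sum of the two
radii. An anisotropic mode emits every 8th slice at z spacing 3 µm to
exercise the interpolation path end to end.

Two modelling choices deserve a note. Nuclei are painted as
`peak · exp(−d²/(2σ²))` with `σ = r/2`, truncated at `2r` rather than at
`r`: a hard cut at `r` would leave a 0.135 × peak cliff at the boundary,
contradicting the gradual-falloff premise the whole method rests on. And
interior fragments are kept weak (0.15 × peak): at that amplitude the
noiseless intensity maximum stays within one voxel of the true centre,
while fragments still perturb the enhanced field enough to exercise the
Stage-3 merging path.

What the phantom does **not** emulate: optical point-spread anisotropy,
depth-dependent attenuation and scattering, autofluorescence texture,
nucleoli-scale structure, or cell division. Passing the recovery tests
therefore shows the pipeline is correct *under its stated model*, not that
it matches manual annotation on real embryo stacks.

## Problem sizes in the tests

Unit tests run oracle comparisons on ≤ 9³ volumes (where brute-force
nested-loop references are exact and fast) and pipeline behaviour on 96³
phantoms with ~6 nuclei. The end-to-end recovery and specificity checks
use a 128³ grid with all 17 nuclei — the same nucleus scale and density as
the full 261×261×224 setting at an eighth of the voxel count, which keeps
a complete generate-run-evaluate cycle around ten seconds on one CPU. The
acceptance script uses the same 128³ setting.

## Known limitations

- **Variant-2 sensitivity near the mask edge.** The hybrid image zeroes
  the LEI outside the Otsu mask, so profiles of small nuclei acquire flat
  (label 0) tails and their Stage-2 scores drop; on phantoms, Variant-2
  trades several missed small nuclei for its cleaner Stage-1 candidate
  set. Variant-1 is the default.
- A fixed scale set tied to one `D_max` under-enhances nuclei that shrink
  markedly over a time series; re-estimating `D_max` per time point is
  outside the current scope, as is temporal linking of centroids.
- Otsu's global threshold can swallow low-contrast nuclei under severe
  illumination non-uniformity; no illumination correction is applied.
- RMSE is computed over matched pairs only; with an empty estimate set it
  is undefined (`NA`) and precision is reported as 0 with a warning.
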