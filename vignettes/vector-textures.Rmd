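---
title: "Vector textures from derivative domains: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector textures from derivative domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vectex)
```

## The model

`vectex` classifies 3D lesions by the *texture of their derivative fields*
rather than of the raw intensity. The reasoning: first- and second-order
derivatives magnify exactly the local contrast variations that distinguish
heterogeneous tissue, and a derivative is naturally a *vector*, carrying
directional information that a scalar gray level discards.

Two vector fields are computed per volume:

1. **Gradient**: `∇I = (I_x, I_y, I_z)` by separable 3D Sobel filtering
   (difference kernel `(-1, 0, 1)` on the derivative axis, smoothing
   `(1, 2, 1)` on the other two).
2. **Hessian eigenvalues**: the six unique second-order partials by
   separable Deriche (exponential-kernel) filtering at scale `α = 1`, then
   the per-voxel eigenvalues of the symmetric 3×3 matrix sorted by signed
   value, `λ₁ ≥ λ₂ ≥ λ₃`, taken as the 3-vector `(λ₁, λ₂, λ₃)`. A real
   symmetric matrix always has real eigenvalues, so this reduction is
   exact, and sorting makes it well defined without any eigenvector
   bookkeeping; ties need no tie-break because only the sorted values are
   used.

Each field is re-expressed in spherical coordinates: magnitude
`|v| = √(v₁² + v₂² + v₃²)`, azimuth
`θ = acos(v₁ / √(v₁² + v₂²))`, plus `π` when `v₂ < 0` (range `[0, 2π]`),
and polar angle `φ = acos(v₃ / |v|)` (range `[0, π]`, measured from the
third axis). Note the azimuth is *not* the `atan2` convention: the
negative-`v₂` branch adds `π` to the principal `acos` value, which is what
makes the identity `|v| cosθ … = v₁` close under the chosen branch rule.

### Quantization into vector texture images

Angles are quantized into `Q` equal half-open bins over their period,
`⌊Q·θ / period⌋`, with the single closed boundary value (`θ = 2π` or
`φ = π`) folded into bin `Q − 1`. The azimuth produced by the `acos`
branch never actually reaches `2π`, but the boundary branch is kept so the
contract is total.

Magnitudes are heavy-tailed (most voxels sit in a narrow band, edges
produce a long tail), so quantizing them uniformly would leave almost all
mass in the lowest bins. Two steps address this:

* **t-th root remapping** `m ↦ m^(1/t)` — strictly monotone and
  rank-preserving, it compresses the tail without the drawback of
  histogram equalization, which flattens away the very differences in
  distribution shape that distinguish lesion types.
* **uniform min–max scaling** over the ROI voxels only,
  `⌊(m − min)·Q / (max − min)⌋` with the maximum folded into `Q − 1`. A
  constant ROI quantizes to all zeros by documented contract. Because the
  scaling is min–max, any global positive rescaling of the input (and any
  fixed normalization constant in the derivative kernels) cancels exactly.

Four VTIs result: angle-only GAV/HAV with channels (azimuth, polar) and
full-vector TGV/THV with channels (magnitude, azimuth, polar), in the
gradient and Hessian domains respectively.

### Vector co-occurrence and texture measures

The vector co-occurrence matrix counts ordered pairs of VTI *states*
(mixed-radix encodings of the channel tuple) at voxel pairs `(p, p + d·u)`
for displacement `d` (default 1) along direction `u`. Of the 26
nearest-neighbour directions only 13 are informative — the matrix along
`−u` is exactly the transpose of the one along `u`, a property the test
suite asserts — and the canonical 13 are fixed in a documented order.
Each matrix is symmetrized (`C + Cᵀ`, the standard Haralick convention),
normalized to a joint probability matrix, and reduced to 28 scalar
measures, giving `13 × 28 = 364` features per lesion per VTI.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `t_root` (gradient) | 2 | — | best-performing root for gradient magnitudes in the package's parameter-study protocol |
| `t_root` (Hessian) | 4 | — | same, for eigenvalue magnitudes |
| GAV levels | (10, 5) | bins | azimuth × polar; best row of the angle-level study |
| TGV levels | (2, 10, 4) | bins | magnitude × azimuth × polar |
| HAV levels | (5, 8) | bins | azimuth × polar |
| THV levels | (5, 3, 8) | bins | magnitude × azimuth × polar |
| `d` | 1 | voxels | nearest-neighbour co-occurrence; exposed but rarely changed |
| `threshold` | −450 | HU | voxels below this are predominately lumen air and are removed from the ROI |
| `alpha` | 1 | 1/voxel | Deriche kernel scale; larger = narrower kernel |
| `ntree` | 5000 | trees | forest size for study-grade runs; tests and sweeps use 500 or less |
| `k_max` | 50 | features | forward-selection cap; selection curves plateau far earlier at tens-of-lesions scale |

All quantization defaults are overridable per kind through
`quant_config()`, and `run_sweep()` reproduces the parameter-study
protocol (grid → mean ± SD AUC) on any cohort.

## Numerical and design choices

* **Degenerate spherical voxels.** `v₁ = v₂ = 0` gives azimuth 0; a zero
  vector gives polar 0 and magnitude 0. The defining expressions are `0/0`
  there; a fixed convention keeps every voxel in the VTI and is
  deterministic. A constant volume therefore produces a gradient VTI
  entirely in state 0.
* **Sobel boundary.** Edge replication. Zero padding would manufacture
  spurious boundary gradients; replication makes the derivative of a
  constant volume exactly zero everywhere including the faces.
* **Deriche realization and normalization.** The exponential-family
  kernels (smoothing `(α|n|+1)e^{−α|n|}`, first derivative `n·e^{−α|n|}`,
  second derivative `(1 − c|n|)e^{−α|n|}`) are applied as separable
  convolutions truncated where the envelope falls below 1e−12 — at
  `α = 1` that is a radius of 28 voxels, numerically equivalent to the
  recursive realization at machine precision. Normalization fixes unit DC
  gain for smoothing, unit ramp response for the first derivative, and
  response exactly 2 to `n²` for the second derivative (zero to
  constants). Any residual fixed constant would cancel in the min–max
  magnitude scaling; only relative values survive into the VTI. Mixed
  partials compose two first-derivative passes.
* **Eigenvalues in closed form.** The trigonometric solution of the
  symmetric 3×3 characteristic polynomial, vectorized over all voxels,
  with the scalar-matrix case (`p = 0`) guarded explicitly. Trace and
  determinant identities against the decomposed eigenvalues hold to 1e−8
  relative and are asserted on random fields.
* **ROI semantics.** The air threshold shrinks only the co-occurrence
  support: derivative kernels read the full volume, so boundary voxels
  keep their true (air) neighbourhood, exactly as a clinical ROI crop
  behaves. Both endpoints of a VCM pair must lie inside the
  (post-threshold) ROI — a single air endpoint would otherwise inject
  lumen states into the matrix. Magnitude min/max are likewise taken over
  ROI voxels only; angle bins are global and fixed, so ROI membership
  cannot affect them. Out-of-ROI voxels in the quantized magnitude grid
  are clamped into range but never enter any pair.
* **Degenerate measures.** `0·log 0 = 0` throughout; logarithms base 2
  (entropies in bits — any fixed base only rescales features, which
  rank-based forests ignore). Correlation-type measures on matrices with
  zero marginal variance, and the maximal correlation coefficient when
  its eigenproblem degenerates, return a sentinel of 0. A direction whose
  matrix is empty (disconnected ROI) contributes 28 sentinel zeros with a
  warning rather than failing the lesion.
* **The 28-measure set.** The battery is the 14 classic Haralick
  statistics plus 14 widely used extensions (autocorrelation, cluster
  prominence/shade/tendency, dissimilarity, maximum probability, the
  inverse-difference family, joint average/variance, inverse variance,
  difference average, and the sum of marginal entropies), fixed in a
  documented order as the named constant `measure_names` so the whole set
  can be swapped coherently. Under the symmetric-matrix convention the
  joint average and variance coincide with the sum-of-squares mean and
  variance; both names are kept for battery stability. Every measure is
  verified against an independent direct-summation oracle to 1e−10.
* **Classification protocol.** Feature ranking (mean decrease in GINI)
  uses the training half only — a leakage-guard test asserts that
  permuting test labels cannot change the selected ordering. Forward
  selection starts at 3 features and takes the smallest `k` on AUC ties
  (parsimony). Operating-point metrics use Youden's J on the test ROC.
  For leave-one-out, a single held-out lesion has no AUC of its own, so
  held-out scores are pooled across all lesions per candidate `k` and one
  pooled AUC per `k` is computed; the best pooled AUC is reported. `mtry`
  stays at the engine default. One master seed spawns per-repetition
  child seeds, making every result bit-reproducible.
* **AUC.** Computed by the package's own trapezoidal sweep, which equals
  the normalized Mann–Whitney statistic with ties counted half; the test
  suite cross-checks it against both an exhaustive pair-counting oracle
  and an independent ROC library.

## What the phantom generator emulates — and what it does not

`make_phantom()` builds a spherical lesion of spatially correlated
Gaussian texture (white noise smoothed with a Gaussian of standard
deviation equal to the correlation length, rescaled to unit variance) on
an air background of −1000 HU. The defaults — 32³ voxels, lesion radius
12, class correlation lengths 1.0 vs 2.5 voxels, contrast amplitudes 120
vs 180 HU around a 30 HU base, ±10 % lognormal per-lesion jitter — are
chosen to emulate large (≥ 30 mm) colorectal lesions on ~1 mm CT: lesions
thousands of voxels in size whose two pathological classes differ
unambiguously in heterogeneity scale. The air background exercises the
−450 HU thresholding path realistically: thresholding the full-volume
mask recovers exactly the lesion sphere.

What the phantoms deliberately do **not** model: anatomical shape
(lesions are spheres), partial-volume mixing at the lesion boundary,
scanner noise spectra and reconstruction kernels, intensity
inhomogeneity, or the size/sex distribution of any clinical cohort.
Passing the pipeline tests on phantoms therefore demonstrates that the
*machinery* — derivative fields, quantization, co-occurrence accumulation,
feature extraction, selection and validation — is correct and
discriminates textures that differ in correlation structure; it does not
certify clinical performance on CT colonography data, which must be
established on real cohorts.

## Problem sizes used by the tests and the acceptance script

Chosen as the package's own working scale: oracle-equivalence checks run
on 8³ VTIs (all 13 directions, displacements 1–2) and 4–16-state
matrices; derivative oracles on 5³–15³ volumes; the discrimination check
uses a 16 + 16 phantom cohort, THV features, 20 twofold repetitions, a
500-tree forest and a forward-selection cap of 20 — small enough to run
in about a minute, large enough that the separable cohort scores near
AUC 1 and the null cohort near 0.5, as `scripts/acceptance.R` recomputes
on every invocation.

## Known limitations

* Voxel spacing is recorded but not used to rescale derivative kernels;
  strongly anisotropic acquisitions would mix physical scales across
  axes. A mm-space kernel mode is a natural extension.
* The Deriche boundary condition (edge replication) and the
  first-derivative composition for mixed partials are this package's
  documented choices among several defensible ones.
* Feature extraction is single-threaded R; volumes beyond ~128³ will be
  slow, and a compiled backend would be the first optimization.
* The forward-selection AUC is an optimistic estimate by construction
  (the selected `k` maximizes the *test* AUC); the protocol is standard
  for small-cohort radiomics but its absolute numbers should be read as
  protocol-relative, and the null-cohort check quantifies the resulting
  bias at chance level.
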