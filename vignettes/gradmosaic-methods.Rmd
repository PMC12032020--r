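---
title: "Local and global cortical organization from multimodal gradient profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local and global cortical organization from multimodal gradient profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradmosaic)
```

# The analysis

`gradmosaic` quantifies how the cortex balances areal specialization
(local organization) against integration along continuous large-scale
gradients (global organization). It works on three vertex-wise connectomes
defined on a spherical surface mesh:

* **MPC** (microstructural profile covariance): depth-wise intensity
  profiles are cross-correlated between vertices with *partial*
  correlations controlling for the cortex-wide mean intensity profile,
  then Fisher r-to-z transformed with non-positive values floored at zero.
  For vertices $i, j$ and mean profile $m$:
  $r_{ij|m} = (r_{ij} - r_{im} r_{jm}) / \sqrt{(1 - r_{im}^2)(1 - r_{jm}^2)}$.
* **FC** (functional connectivity): Pearson correlation of vertex
  timeseries, Fisher r-to-z transformed.
* **SC** (structural connectivity): consumed as a precomputed nonnegative
  matrix.

Each matrix is row-sparsified (default: top 10% of off-diagonal entries
per row), converted to a normalized-angle affinity
$A_{ij} = 1 - \arccos(c_{ij})/\pi$ with $c_{ij}$ the cosine similarity of
connectivity rows, and embedded with a diffusion map (anisotropic
normalization exponent $\alpha = 0.5$, 10 components, diffusion time 0 so
components are scaled by $\lambda/(1-\lambda)$). The first five gradients
of each modality are normalized to $[-1, 1]$ by their maximum absolute
value and stacked into a vertex-by-15 array. Averaging within the areas of
a probabilistic atlas (argmax labeling, ties to the lowest area index)
yields the **area-wise gradient profile matrix**, the central object of
the analysis.

From the profiles the package computes:

* **Inter-areal dissimilarity** — mean cosine distance of each area's
  profile to all other areas (the row mean of the cosine distance matrix);
* **Intra-areal dissimilarity** — cosine distance of each vertex's
  gradient vector to its own area's mean profile;
* **Similarity affinity and clustering** — $1 -$ cosine distance between
  profiles, clustered agglomeratively (average linkage) with the number of
  clusters chosen by maximum mean silhouette;
* **Cross-task diversity** — for each vertex, the mean cosine distance
  between its whole-brain FC rows across task states;
* **Intra-areal cross-task SD** — the per-vertex SD across tasks of the
  mean within-area FC, averaged over the area's vertices;
* **Inference** — spherical spin-permutation nulls for extreme-area
  detection, (partial) Spearman associations, hierarchy-level t-contrasts
  with Cohen's d and FDR, participation coefficient and global FC
  strength.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `keep_fraction` | 0.10 | per-row sparsity before the affinity (robustness grid 0.5–0.9 supported) |
| `n_components` | 10 | diffusion-map components computed |
| `alpha` | 0.5 | anisotropic normalization exponent |
| `k_per_modality` | 5 (range 3–7) | gradients retained per modality |
| `n_perm` | 1000 | spin permutations |
| `fdr_q` | 0.05 | Benjamini–Hochberg level |

Defaults follow standard gradient-analysis practice for cortical
connectomes. All randomness flows from one seed through stage-named child
seeds (`child_seed`), so any stage can be rerun in isolation and full runs
are byte-reproducible.

# The synthetic cortex

Because the statistics above are meaningful only relative to ground truth,
the package ships a generator (`make_sphere_mesh`, `make_parcellation`,
`make_smooth_field`, `make_multimodal_dataset`) that emulates the
statistical structure the analysis assumes:

* **Mesh** — an icosphere per hemisphere ($V = 10 \cdot 4^L + 2$); level 3
  (642 vertices/hemisphere) for simulation studies, level 4 as the routine
  default, level 5 as the `paper_scale` preset. A mesh of exactly 4432
  vertices per hemisphere (the fsLR-5k convention) is not reachable by
  icosahedral subdivision, so the preset brackets that resolution from
  above. A 2% polar cap plays the mid-wall (medial wall) role and is
  excluded from all aggregation.
* **Parcellation** — farthest-point-sampled seeds, geodesic Voronoi
  labels (graph shortest paths over edge lengths), softmax probabilities
  with temperature `softness` (0 = hard atlas).
* **Planted axes** — smooth Gaussian fields (iterated neighbourhood
  averaging, standardized; iteration count $(\ell/h)^2$ for correlation
  length $\ell$ and mean edge length $h$). Axis 1 is the sensory-fugal
  analogue; hierarchy labels are its area-level quartiles in the order
  idiotypic, unimodal, heteromodal, paralimbic, and the histological
  gradient is its area average plus noise (SD 0.1).
* **Modalities** — every planted axis $j$ enters each modality through a
  monotone angle $\theta_j \in [0, \pi/2]$ (rank-uniform in the axis) with
  geometrically decaying amplitude: depth profiles mix orthogonal cosine
  basis pairs by $(\cos\theta_j, \sin\theta_j)$ (MPC amplitude
  $0.2^{j-1}$); timeseries mix shared latent source pairs the same way (FC
  amplitude $0.3^{j-1}$); SC decays exponentially in chord distance (scale
  radius/2, plus a $2r$ inter-hemispheric penalty since both hemispheres
  are concentric spheres) modulated by $e^{-0.4^{j-1}|\Delta\theta_j|}$.
  Secondary amplitudes are weakest for MPC because its floored
  partial-correlation kernel is spatially local and most sensitive to axis
  mixing, and strong enough overall that gradients beyond the first carry
  stable signal — which is what makes dissimilarity maps reproducible
  across sparsity thresholds, as they are in real cortical data.
* **Tasks** — task scans shift the FC mixing angle by a smooth
  "flexibility" field times a per-task offset; the timeseries noise
  realization is shared across scans, so zero flexibility yields exactly
  identical task FC — an exact negative control for the diversity
  statistics. `make_task_fc_stack` additionally provides an additive
  perturbation model in which cross-task SD is exactly linear in the
  perturbation amplitude.
* **Noise** — per-modality SNR (default 4; `Inf` = noise-free) divides
  unit-variance Gaussian noise into profiles and timeseries and applies
  symmetric log-normal jitter to SC.

## What the generator does and does not show

The generator reproduces the *relational* structure the method relies on —
smooth planted axes, correlation decaying with axis distance, depth
profiles whose shape drifts along the axis, distance-dependent SC,
probabilistic parcels, task-dependent connectivity — but none of the
biophysics: no folded geometry, no hemodynamics, no realistic myelin
values. Passing tests therefore demonstrate that the pipeline recovers
planted organization under its own assumptions, not that any particular
empirical brain result is correct.

Two measured properties of the synthetic system are worth knowing. First,
noise-free recovery of a single planted axis by the principal MPC gradient
plateaus near $|\rho| \approx 0.99$ rather than reaching 1: the partial
correlation controlling the mean profile centers the residual profile
bundle, so the non-positive floor always activates, the MPC kernel is
spatially local, its leading eigenvalues are nearly degenerate, and
boundary discretization mixes the top modes slightly. FC, whose kernel is
global, recovers the axis essentially perfectly. Second, with the default
two-axis generator the first MPC gradient trades a little axis-1 purity
for secondary structure (recovery $\approx 0.95$ at SNR 8), degrading
monotonically as SNR falls.

# Numerical choices

* Correlations are clipped to $\pm(1 - 10^{-6})$ before Fisher z, bounding
  duplicated-series values without reordering finite ones.
* Vertices whose profiles are constant *or collinear with the mean
  profile* are excluded from MPC (their partial correlation is undefined)
  and reported in the connectome's exclusion list.
* Sparsification keeps `ceiling(f (n-1))` entries per row; ties at the
  cutoff resolve to the lower column index, making runs deterministic.
* Eigenvector signs are fixed so each component's maximum-|value| entry is
  positive, removing eigensolver sign ambiguity ahead of Procrustes
  alignment (a single orthogonal fit after column centering, no scaling).
* Permutation p-values use the $(\text{count}+1)/(n+1)$ estimator, so they
  are never zero; two-sided extreme-area p-values are
  $2\min(p_\text{high}, p_\text{low})$ capped at 1, then BH-corrected.
* Hierarchy contrasts use the pooled-variance Student t with
  t-distribution CIs; zero pooled variance flags the contrast and reports
  signed infinite d rather than failing.
* The spin test projects area values to vertices, applies a uniform random
  rotation (mirrored between hemispheres to preserve left/right
  correspondence), resamples by nearest rotated vertex and re-aggregates
  under the *fixed* labeling — preserving area count and sizes in every
  permutation. Rotating the labeling itself would drop or duplicate areas
  permutation by permutation; the fixed-labeling variant avoids that
  bookkeeping and leaves the observed map exactly reproducible under the
  identity rotation. Rotation index sets depend only on mesh and seed and
  are reusable across maps (`spin_rotation_indices`).
* The partial Spearman residualizes ranked maps on the ranked covariate;
  a map collinear with the covariate is defined to have zero partial
  correlation.
* The intra-areal size adjustment regresses ranked area means on ranked
  vertex counts and reports residuals alongside the raw means, since the
  adjustment itself is a methodological free choice.
* The clustering criterion is the mean silhouette width (ties toward
  fewer clusters); the group template averages raw connectome matrices
  before sparsification and affinity.

# Simulation sizes

Simulation studies in the test-suite and the bundled acceptance script use
level-2 meshes (162 vertices/hemisphere, 16 areas) for repeated full
pipeline runs, level-3 meshes (642/hemisphere, 40–48 areas) for recovery,
calibration and the smoke configuration, 200–1000 spin permutations, and
SNR levels 8/2/0.5 for the degradation ladder. These sizes were chosen so
a complete study runs in minutes on a laptop while keeping all planted
effects comfortably detectable.

# Known limitations

* Geodesics are graph shortest paths over mesh edges, a slight
  overestimate of true spherical geodesics; adequate for parcellation and
  generator purposes.
* The generator's hemispheres are statistically symmetric; no lateralized
  effects are planted.
* The intra-areal size adjustment and the clustering criterion are
  conventions, exposed so alternatives can be substituted.
* Spin nulls are approximate for maps whose autocorrelation is anisotropic
  on the sphere; calibration was verified empirically (type-I error about
  4–5% at nominal 5%) for isotropic smooth maps.

# A worked run

```{r, eval = FALSE}
cfg <- gm_config(simulate = list(subdivision_level = 3, n_areas = 40,
                                 n_tasks = 3),
                 n_perm = 200, seed = 17)
report <- run_pipeline(cfg)
report
head(report$area_table)
report$correlations$inter_vs_cross_task_diversity
```
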