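# gradmosaic

Local versus global cortical organization from multimodal connectome
gradients.

Cortical areas are classically treated as discrete, internally homogeneous
units, while connectome gradients describe the cortex as a set of smooth,
continuous axes. `gradmosaic` implements an analysis that joins the two
views: it builds vertex-wise microstructural (MPC), structural (SC) and
functional (FC) connectomes, derives diffusion-map gradients from each,
averages them inside the areas of a probabilistic parcellation into
**area-wise multimodal gradient profiles**, and then asks how distinct each
area is from the rest of the cortex (inter-areal cosine dissimilarity), how
homogeneous it is inside (intra-areal dissimilarity), how its connectivity
reconfigures across task states (cross-task diversity), and whether these
patterns align with the four-level sensory-fugal hierarchy — all with
spherical spin-permutation inference that respects spatial autocorrelation.

It is intended for researchers in network neuroscience who want the full
pipeline — connectome construction, gradient embedding, arealization,
dissimilarity statistics, spin tests — as tested, seedable building blocks,
together with a synthetic cortical data generator so every stage can be
validated against planted ground truth without any imaging data.

## The core quantities

With area profiles $p_a$ (each the within-area mean of 3 modalities × 5
max-abs-normalized diffusion gradients):

* inter-areal dissimilarity of area $a$: mean over $b \ne a$ of
  $1 - \cos(p_a, p_b)$;
* intra-areal dissimilarity of vertex $v$ in area $a$:
  $1 - \cos(g_v, p_a)$ for the vertex gradient vector $g_v$;
* cross-task diversity of vertex $v$: mean cosine distance between $v$'s
  whole-brain FC rows across task states;
* significance: observed maps compared against nulls generated by random
  rotations of the sphere (mirrored across hemispheres), with
  (count+1)/(n+1) permutation p-values and Benjamini–Hochberg correction.

MPC uses partial correlations of depth-wise intensity profiles controlling
for the cortex-wide mean profile, Fisher-z transformed and floored at zero;
FC uses Fisher-z Pearson correlations; embeddings use normalized-angle
affinities ($1 - \arccos(c)/\pi$) and diffusion maps with $\alpha = 0.5$.

## Worked example

```r
library(gradmosaic)

cfg <- gm_config(simulate = list(subdivision_level = 3, n_areas = 40,
                                 n_tasks = 3),
                 n_perm = 200, seed = 17)
report <- run_pipeline(cfg)
report
#> gm_report: 40 areas | mean inter 1.0246 | mean intra 0.3616 | PC1 44.5% | k = 2

head(report$area_table[, c("area", "inter_dissimilarity",
                           "intra_dissimilarity", "hierarchy")], 4)
#>   area inter_dissimilarity intra_dissimilarity   hierarchy
#> 1   A1            1.022223           0.4672329 heteromodal
#> 2   A2            1.029505           0.4358516 heteromodal
#> 3   A3            1.011077           0.2970462   idiotypic
#> 4   A4            1.008439           0.2761736   idiotypic
```

The run simulates a level-3 bi-hemispheric icosphere cortex (642 vertices
per hemisphere) with a planted sensory-fugal axis, 40 Voronoi areas and 3
task scans, then executes the full analysis. The mean intra-areal
dissimilarity (0.36) sits far below the inter-areal mean (1.02) — areas are
internally much more homogeneous than they are distinct from one another,
which is the qualitative signature the area profiles are designed to
capture (and here reflects the parcellation being aligned with the planted
structure). The principal component of the profile matrix explains 44.5%
of the variance and orders areas along the planted axis; idiotypic areas
(planted sensory end) show the lowest intra-areal dissimilarity in this
draw. Per-area flags for significantly extreme areas, hierarchy-level
t-contrasts and spin-corrected Spearman associations are in
`report$area_table`, `report$contrasts` and `report$correlations`.

A thin command-line front end is included at `inst/cli/gradmosaic.R`
(`simulate`, `run`, `sweep` subcommands over YAML configs).

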