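# otolithmorph

Joint 3D geometric morphometrics of the inner-ear **otolith system**:
linking the external bony vestibule to the internal membranous utricle
and saccule.

The utricle and saccule sense linear acceleration and head tilt; the
orientation of their sensory maculae sets each organ's directional
coding. Soft tissue is almost never available in skeletal or fossil
material, so the scientific question this package addresses is whether —
and how well — the bony wall of the vestibule predicts the membranous
anatomy inside it. It provides a complete, tested workflow for

* **joint Procrustes shape analysis** — one Generalized Procrustes
  superimposition of 22 single landmarks + 86 sliding semilandmarks
  (5 curves), *then* a split into bony and membranous blocks (the
  "within a configuration" approach, preserving relative position and
  scale), with bending-energy-minimizing semilandmark sliding;
* **covariation statistics** — OLS regression batteries of block-wise
  PC1 scores and log centroid sizes (11 shape + 15 size models),
  two-block partial least squares (2B-PLS) integration tests and
  covariance-ratio (CR) modularity tests with seeded permutation nulls;
* **maculae orientation** — best-fit planes through bony landmark triads
  versus macular planes, inter-plane angles in each specimen's original
  anatomical frame, and the bony-vs-macular angle regression;
* **SPHARM shape modeling** — real spherical-harmonic point-distribution
  models of genus-0 surfaces (degree ladder 1–25), first-order-ellipsoid
  correspondence alignment, mean shapes, Taubin smoothing;
* **morphometric model assembly** — similarity fiducial registration of
  mean meshes onto the consensus landmarks and a voxel-boolean
  perilymphatic "negative-space" mesh;
* **soft-tissue reconstruction** — thin-plate-spline warping of the
  model to any specimen's bony landmarks LM1–LM10, with closest-point
  mesh-distance validation against true organ surfaces and a Wilcoxon
  rank-sum efficacy test;
* a **synthetic labyrinth generator** with controlled bone–membrane
  covariation (target R²), integrated/modular/null covariance modes,
  known macular plane offsets, and genus-0 mesh trios — the ground-truth
  test bed for every stage.

In standard notation: configurations are superimposed by minimizing
Σ‖X<sub>i</sub> − c<sub>i</sub>R<sub>i</sub>X̄ − 1t<sub>i</sub>ᵀ‖²;
semilandmarks slide along curve tangents minimizing the TPS bending
energy yᵀBy (3D kernel U(r) = r); integration is the correlation r-PLS
of the first singular pair of the cross-block covariance S₁₂; modularity
is CR = ‖S₁₂‖<sub>F</sub> / √(‖S₁₁°‖<sub>F</sub>‖S₂₂°‖<sub>F</sub>)
with within-landmark blocks excluded; surfaces are x(u) = Σ c<sub>lm</sub>
Y<sub>lm</sub>(u) per coordinate on the unit sphere.

## Worked example

Generate a 12-specimen synthetic population with bone–membrane
covariation at R² = 0.5 and 4.6° macular plane offsets, superimpose,
slide, and test:

```r
library(otolithmorph)

pop <- generate_population(population_spec(n_specimens = 12, seed = 42))
ga  <- gpa(lapply(lapply(pop, `[[`, "config"), resample_config_curves))
ga  <- slide_semilandmarks(ga)
ga
#> aligned_shapes: 12 specimens x 108 landmarks (GPA converged in 3 iterations)

blocks <- subset_blocks(ga, landmark_set(1))
ols_regress(shape_pca(blocks$membranous)$scores[, 1],
            shape_pca(blocks$bony)$scores[, 1])
#> ols_fit: slope -0.9791, R2 0.452, p 0.0166 (n = 12)

two_block_pls(blocks$bony, blocks$membranous, n_perm = 999, seed = 1)
#> 2B-PLS: r-PLS 0.790, z 1.15, p 0.148 (999 permutations)

modularity_cr(blocks$bony, blocks$membranous, n_perm = 999, seed = 1)
#> modularity CR: 0.764, z -34.18, p 0.001 (999 permutations)

ang <- maculae_orientation_analysis(lapply(pop, `[[`, "config"))
subset(ang$summary, name %in% c("u_246_triad", "s_8910_triad"))
#>           name  n mean_deg   sd_deg   min_deg  max_deg
#> 1 s_8910_triad 12 5.761656 2.625535 1.3996226 9.499103
#> 3  u_246_triad 12 4.959933 2.476496 0.8702745 9.075200
```

Reading the output: the bony PC1 ~ membranous PC1 regression recovers an
R² of 0.45 against the generator's target of 0.5 (n = 12, so individual
draws scatter widely); the 2B-PLS correlation is high (0.79) but, with
12 specimens and >300 variables, not individually significant at this
seed; the CR of 0.76 with a lower-tail p of 0.001 flags the macular
plane dispersion as modular structure; and the bony triads {2,4,6} and
{8,9,10} approximate their maculae to a mean of ~5°, matching the
generated 4.6° offset within sampling noise.

The full analysis order — simulate/ingest, resample + GPA + slide,
regression battery, maculae angles, integration/modularity per landmark
set, SPHARM mean shapes, model assembly, reconstruction validation —
is orchestrated by `run_pipeline(pipeline_config(seed = 1))`, which
writes a deterministic CSV/JSON/OBJ report bundle. A thin command-line
wrapper is included at `inst/cli/otolith.R`
(`Rscript otolith.R simulate|run-all|reconstruct ...`).

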