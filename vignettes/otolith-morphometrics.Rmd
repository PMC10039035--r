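---
title: "Joint morphometrics of the otolith system: models, parameters, and design choices"
author: "otolithmorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint morphometrics of the otolith system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otolithmorph)
```

## The scientific problem

The otolith organs (utricle and saccule) are membranous sacs suspended in
the bony vestibule of the inner ear. Their shape and, above all, the
orientation of their sensory maculae govern how linear acceleration and
head tilt are encoded. Soft tissue does not fossilize and is rarely
preserved in skeletal collections, so a long-standing question is whether
the *external* bony wall of the vestibule carries enough information to
recover the *internal* membranous anatomy. This package implements a
complete joint-morphometrics workflow for that question:

1. **Joint shape space.** Bony and membranous landmarks of each specimen
   are superimposed *together* (one Generalized Procrustes Analysis of the
   full configuration) and only then split into tissue blocks — the
   "within a configuration" approach. This preserves the relative size and
   position of the blocks, which is exactly the signal of interest.
2. **Covariation statistics.** Ordinary least-squares regressions of
   block-wise principal components and log centroid sizes; two-block
   partial least squares (2B-PLS) with permutation tests of integration;
   the covariance ratio (CR) with landmark-permutation tests of
   modularity.
3. **Maculae orientation.** Best-fit planes through bony landmark triads
   are compared with planes through the macular landmarks or macular
   surfaces; the inter-plane angle measures how well bone approximates the
   functional orientation of each macula.
4. **Mean-shape modeling.** Genus-0 surfaces of the vestibule, utricle and
   saccule are described by real spherical harmonics (a SPHARM-PDM-style
   point-distribution model), averaged across specimens, and registered
   onto the consensus landmark configuration by similarity fiducial
   registration.
5. **Soft-tissue reconstruction.** The assembled model — mean meshes, the
   voxel-boolean "negative space" perilymph surface, and bony landmarks
   LM1–LM10 in the model frame — is warped by a 3D thin-plate spline onto
   any specimen's bony landmarks, predicting that specimen's membranous
   organs. Closest-point mesh distances and a Wilcoxon rank-sum test
   quantify whether reconstructions are closer to the truth than
   specimens are to each other.

All of this is exercised end-to-end on a synthetic labyrinth generator
with known ground truth, described below.

## The landmark scheme

The canonical configuration has 22 single landmarks and 86 sliding
semilandmarks on five curves (108 points): bony LM1–LM10 plus two bony
curves (SemiLM1, and SemiLM2 around the oval window), membranous
LM11–LM22 plus three membranous curves (SemiLM3 on the utricle, SemiLM4
and SemiLM5 tracing the utricular and saccular macular contours).
LM17–LM19 and LM20–LM22 are the utricular and saccular macular triads.
Six analysis sets re-select these points: the full set; the full set
without SemiLM2; singles only; singles without LM5 (the most variable
landmark); additionally without LM7; and a split into greater-utricle
versus greater-saccule modules. The per-curve point counts (20, 18, 16,
16, 16) are package defaults chosen to total 86.

Point order is the homology contract: index *i* is the same anatomical
point in every specimen, validated by label equality, never by geometry.

## Superimposition and sliding

`gpa()` performs classical full-Procrustes superimposition: each
configuration is centered, scaled to unit centroid size (sizes are stored
pre-scaling for the size battery), and iteratively rotated to the evolving
consensus until the change in the total Procrustes sum of squares falls
below `1e-10` (at most 100 iterations). Reflections are never introduced
(`det(R) = +1`); left/right structures must be mirrored explicitly
upstream. Tangent-space projection is available (`tangent_project`) but
off by default: raw Procrustes residuals enter the statistics. The
reported consensus is the pointwise mean of the aligned coordinates.

`slide_semilandmarks()` minimizes thin-plate-spline bending energy
relative to the consensus. For each specimen, semilandmark displacements
are restricted to the local curve tangent (central differences,
endpoints anchored), the linearized tangential minimum is solved in one
shot per pass, points are snapped back onto the specimen's curve
polyline, and any update that would *increase* a specimen's energy is
rejected — so the within-pass energy trace is non-increasing by
construction. The set is re-superimposed after every pass; five passes
with a `1e-6` relative-energy tolerance are the defaults. The 3D kernel
is U(r) = r throughout; with this kernel the quadratic form w'Kw is
negative semidefinite on the affine-orthogonal subspace, so the bending
energy is its negation.

Numerical notes that matter in practice: kernel distance matrices are
assembled from explicit coordinate differences (the expanded-square
shortcut loses ~8 significant digits for nearby points), the TPS system
is solved exactly with one step of iterative refinement, and Tikhonov
regularization (`1e-8`) is applied only when the interpolation system is
numerically singular, e.g. for coplanar sources.

## Statistics

* `ols_regress()` wraps `stats::lm`; p-values come from the F-test of
  zero slope. The default battery has 11 shape models (bony PC1 regressed
  on membranous PC1 across the six sets and organ-wise splits) and 15
  log-centroid-size models pairing five bony with four membranous
  single-landmark subsets — 26 rows. The exact pairings are package
  defaults with the documented counts.
* `two_block_pls()` takes the SVD of the cross-block covariance; r-PLS is
  the correlation of the first-pair scores. The permutation null (default
  10,000 permutations) permutes specimen rows of the second block; the
  add-one estimator `(1 + #{perm >= obs})/(n_perm + 1)` gives the
  upper-tail p; the effect size z standardizes the observed statistic
  against the permutation distribution. The computation works in the
  n-dimensional row space (QR reduction), so permutations cost an
  n-by-n SVD regardless of landmark count.
* `modularity_cr()` computes CR, the Frobenius norm of the between-module
  covariance over the within-module norms. The within-module norms
  exclude the within-*landmark* diagonal blocks: for one-dimensional
  units this is the ordinary diagonal exclusion, and the block form makes
  CR invariant to rotations of the coordinate frame, which the scalar
  exclusion is not. The null permutes whole landmarks between modules of
  the original sizes; small CR indicates modularity, so p is lower-tail.
  The RV coefficient is deliberately not offered: its sensitivity to
  sample size and variable count is the reason effect sizes and CR are
  used instead.
* `wilcoxon_rank_sum()` delegates to `stats::wilcox.test` (midranks;
  exact enumeration when both samples have at most eight untied values,
  otherwise the normal approximation with continuity correction).

A sign convention makes PC scores reproducible: each loading's
largest-magnitude element is made positive.

## Maculae orientation

Planes come from landmark triads (exact cross-product normal) or from
point clouds (total least squares via the smallest principal direction).
Angles are folded to [0°, 90°] by the absolute normal dot product and are
computed in each specimen's **original, unsuperimposed frame**, because
orientation relative to the surrounding bone is the quantity of interest.
The default comparison table holds the eight bony-vs-macular pairings
(utricular triads {2,4,5} and {2,4,6} against the LM17–19 triad or the
macular surface; saccular triad {8,9,10} and the spherical-recess surface
selection against LM20–22 or the saccular surface). The spherical-recess
selection is a user-supplied point set: no automatic recess detection is
attempted. The closing regression relates the bony inter-plane angle
({2,4,6} vs {8,9,10}) to the inter-macular angle ({17–19} vs {20–22})
across specimens.

## SPHARM modeling

`spherical_parametrize()` maps a validated closed genus-0 mesh (Euler
characteristic 2, every edge in exactly two faces) onto the unit sphere.
The initial map is the radial projection about the centroid; if any
spherical triangle is inverted (non-star-shaped surfaces) the map is
relaxed by on-sphere Laplacian smoothing until no triangle flips. This is
a deliberate simplification of area-preserving optimizers: correctness is
established by round-trip properties (exact degree-1 spheres, monotone
degree ladders, coefficient recovery), not by bit-parity with any
external tool, and the residual area distortion is reported so strongly
non-spherical shapes can be flagged. The oblong, flattened utricle is the
stress case: its parametrization is valid but more distorted than the
saccule's, which is why the default degree map fits the utricle at
degree 15 and the vestibule and saccule at degree 25 (`spharm_degrees`).
Degrees above 25 are not used: with a few thousand vertices the extra
coefficients chase parametrization noise rather than shape.

The basis is the real, Condon–Shortley-free, orthonormal spherical
harmonic set, ordered l ascending and m from −l to l; the normalization
lives in one place (`sph_basis`). Fits are per-coordinate weighted least
squares with per-vertex parameter-sphere Voronoi-area weights, so the
reported RMSE is area-weighted and non-increasing along any nested degree
ladder (1, 2, 3, 4, 5, 10, 15, 25 is the standard series).
`correspondence_align()` rotates each model's parameter sphere so the
first-order (degree-1) ellipsoid axes coincide, with a deterministic axis
order and sign convention, then refits; `pdm_sample()` evaluates models
at icosahedral subdivision directions — the same directions for every
model at a given level, which is the correspondence contract.
`mean_shape()` is the pointwise average of corresponded samples.
`taubin_smooth()` provides the standard λ/µ smoothing
(defaults λ = 0.5, µ = −0.53, 10 steps).

## Model assembly and reconstruction

`assemble_model()` registers each mean mesh onto the consensus landmark
frame by closed-form similarity fiducial registration (Umeyama's
solution; reflections excluded) using the fiducial landmarks carried on
each mesh. The model frame is the consensus scaled by the mean centroid
size, so coordinates stay in mm and voxel sizes keep physical meaning.
The perilymphatic "negative space" is built the way labelmap workflows
do it: all three surfaces are voxelized on one grid (vertical-ray parity
counting; default voxel 0.05 mm), organ voxels are boolean-subtracted
from vestibule voxels, and the boundary surface of the remaining set is
extracted. Organ surfaces are additionally carried as tagged submeshes
(the mean utricle and saccule), replacing any manual removal of bony
topology in a sculpting tool.

`reconstruct_organs()` fits an interpolating TPS from the model's LM1–10
to a target's LM1–10 and maps the organ submeshes through it; the warp
reproduces the landmarks exactly, and affine transforms exactly, by the
classical TPS properties. `validate_reconstruction()` compares pooled
reconstruction-error distances (one-directional, modeled → original,
point-to-triangle) against pooled inter-specimen distances after
landmark-based similarity alignment of all specimens onto a reference —
landmark registration is the documented substitute for surface-based
registration. Distances below 1 nm are floored to zero before the
rank-sum comparison so that degenerate all-zero comparisons return p = 1
rather than amplifying floating-point noise.

## The synthetic labyrinth generator

`generate_population()` defines the study conditions every test runs
under. Defaults: 12 specimens; a 2.0 × 1.7 × 1.5 mm vestibule ellipsoid
enclosing a flattened, oblong ("pancake-like") utricle and a rounder,
sac-like saccule; the full 108-point scheme placed parametrically on the
surfaces (homology exact by construction); per-specimen shape deviations
as smooth degree-2–3 spherical-harmonic radial fields with amplitude
0.05; bone–membrane covariation controlled by a two-factor model whose
bony factor f and membranous factor m correlate so the regression R² of
the factor scores equals `bone_membrane_r2` (default 0.5, the middle of
a plausible 0.3–0.6 band); macular triads and contours placed on planes
tilted from the base bony triad planes by `plane_offset_deg` (default
4.6°) plus factor-driven dispersion (sd 1.9°); isotropic landmark noise
of 0.008 mm, an order of magnitude below the per-landmark deformation
signal; and genus-0 icosphere-based mesh trios deformed by the same
fields as the landmarks.

Covariance modes:

* **integrated** — one bony and one membranous factor with the requested
  correlation; every latent source, including the macular tilts, loads on
  these factors. Optional `jitter_sd` adds a per-specimen global strain
  (symmetric, traceless linear map of the whole labyrinth): variation
  common to every landmark at full strength, hence non-modular, and —
  being linear — exactly recoverable by a landmark-driven TPS. A smooth
  *field* shared across structures would not serve here: evaluated on
  separate parameter spheres its correlation decays with parameter
  distance, which is precisely modular structure.
* **modular** — independent greater-utricle and greater-saccule factors
  (the bony vestibule field is hemispherically weighted by a degree-1
  factor so the bony points near each organ follow that organ's factor);
  true module labels follow the set-6 split.
* **null** — no per-specimen structure of any kind: plane offsets frozen
  at their mean and factor amplitudes zero, so isotropic landmark noise
  is the only variation and landmarks are exchangeable. This is the
  regime under which the permutation tests must hold their nominal
  type-I error.

One deliberate trade-off: macular planes are placed relative to the
**base** bony triad planes, not the specimen's deformed ones. Deformed-
plane placement would make the constructed offsets exact, but it couples
macular orientation deterministically to the bony shape factor and
inflates the delivered bone–membrane R² beyond the requested target —
the covariance budget takes precedence. The price is a small positive
bias in recovered offsets (the deformation tilt of the measured bony
plane folds into the angle): under default conditions roughly +0.7°
(utricular) and +1.6° (saccular) at a 4.6° offset, shrinking as the
offset grows.

What the generator does **not** emulate: real μCT segmentation artifacts,
observer-specific landmark placement bias, high-dimensional individual
variation (deviations here are low-rank, so the *minimum* pairwise
Procrustes distance between individuals approaches the landmark-noise
floor — a property real populations do not share), fixation shrinkage, or
absolute anatomical dimensions (sizes are plausible-mm constructions, not
measurements). Passing tests therefore demonstrate correctness of the
algorithms and calibration of the statistics under controlled conditions,
not anatomical fidelity.

## Calibration results and problem sizes

The test suite runs the statistical calibration at n = 12 specimens with
499 permutations and 1,000 null replicates: the PC1 regression, 2B-PLS
and CR tests all hold rejection rates near 0.05. The PC1 regression sits
at the high side (≈0.06–0.07): joint superimposition fits seven
similarity parameters to both blocks at once and thereby couples them
weakly even under the null — a genuine property of the "within a
configuration" approach worth remembering when interpreting borderline
p-values. R² recovery uses 20 seeded populations at the target 0.5;
plane-offset recovery uses constructed offsets of 5°, 10° and 30°
(exact when noiseless, within 1° under the default noise); the
leave-one-out reconstruction efficacy test mirrors the five-specimen
design with 20 seeds at subdivision-2 meshes; SPHARM checks run the
degree ladder to 25 on subdivision-4 spheres. These sizes keep the whole
suite within a few minutes on one core while leaving every Monte-Carlo
band non-trivial.

## Known limitations

* Curve semilandmarks only; surface (2D-manifold) sliding is not
  implemented.
* Two-module CR only; no multi-module partitions.
* The spherical parametrization targets star-shaped-to-moderately-bent
  genus-0 surfaces; extreme protrusions may need more relaxation
  iterations and will show in the area-distortion diagnostic.
* No phylogenetic comparative machinery; specimens are treated as
  independent.
* The voxel-boolean perilymph surface is a boundary-face extraction at
  voxel resolution; its vertices lie within half a voxel of the true
  walls, which is adequate for volume and containment checks but not for
  curvature analysis.
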