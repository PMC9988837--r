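---
title: "Genetic and phenotypic ancestry correction for dense facial landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic and phenotypic ancestry correction for dense facial landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphancestry)
```

## The problem

Faces vary systematically between geographic populations, and in studies of
facial genetics this ancestry signal confounds association tests unless it is
removed from the phenotype. Two correction traditions exist. The *genetic*
route regresses facial shape on the leading principal components of the
genotype matrix (genetic PCs) and keeps the residuals. The *anthropological*
route subtracts a regional *consensus face* — the mean configuration of a
reference group — from each individual. morphancestry implements both routes
on dense quasi-landmark representations (thousands of template-defined
surface points in correspondence across individuals), quantifies what each
genetic PC does to the face, tests it with permutations, and compares the two
corrections landmark by landmark.

Because real facial-scan cohorts of this kind are consent-restricted, the
package ships a synthetic cohort generator with known ground truth. Every
stage of the pipeline is exercised and validated against that generator; the
package's empirical claims are exactly those its test suite and
`scripts/acceptance.R` compute.

## Pipeline and model

The analysis proceeds in the following stages, each an exported function:

1. **Regional assignment** (`assign_max_region`, `median_threshold_filter`,
   `balanced_subsample`). Individuals are labeled with the region of their
   largest supervised admixture proportion (ties to the first column, for
   determinism); each regional group is thresholded at the *median* of its
   members' maximum proportions (inclusive, midpoint interpolation for even
   counts); a fixed number per region (default 186) is then drawn uniformly
   without replacement, via a seeded shuffle over lexically sorted ids so the
   draw is independent of row order.
2. **Symmetrization** (`symmetrize`). Each configuration is averaged with its
   reflection (x negated) after relabeling bilateral landmark pairs. The
   result is an exact fixed point of `reflect_and_pair` and the operation is
   idempotent. The reflected copy is averaged directly in template space,
   without an extra rigid alignment: registered configurations already share
   the template frame.
3. **Generalized Procrustes analysis** (`gpa`). Configurations are centered,
   scaled to unit centroid size, and iteratively rotated to the evolving mean
   (SVD orthogonal-Procrustes solution with determinant correction, so no
   reflections are introduced) until the root-mean-square change of the mean
   falls below `tol = 1e-8`. Centroid size is recorded *before* scaling,
   because it later enters the covariate model while the analysis itself is
   scale-free. The converged frame is anchored to the configuration with the
   smallest id, which makes output coordinates reproducible and row-order
   invariant.
4. **Covariate correction** (`fit_plsr`, `correct_shapes`). The
   `n x 3L` coordinate matrix is regressed on sex, age, age squared, height,
   weight, centroid size and camera system via partial least squares
   regression (PLS2, SIMPLS algorithm), and each face is replaced by its
   residual plus the grand mean. Predictors are standardized internally
   (their units are heterogeneous: years, cm, kg, ±1 codes); responses are
   centered only, since landmark coordinates share one unit.
5. **Ancestry correction and effects** (`ancestry_correct`,
   `single_pc_effect`). The covariate-corrected faces are regressed on the
   first `k = 4` genetic PCs; the displacement before minus after correction
   is the *genetic facial ancestry effect*, per individual and averaged per
   region. The effect of a single PC is the difference between correcting
   with all `k` PCs and with `k - 1` (one excluded). Effects are multiplied
   by 4 (regional) or 8 (single-PC) only at visual export
   (`exaggerate`), never inside statistics.
6. **Permutation testing** (`shape_pca`, `total_r2`, `permutation_test`,
   `subgroup_tests`). Shape is reduced by PCA, retaining components up to
   96% cumulative variance; scores are normalized to unit variance with the
   eigenvalues kept. The statistic is the total R² of the retained scores on
   a predictor set (full-component PLSR, which coincides with least
   squares). The null is built by re-pairing predictors with shapes B =
   10,000 times; `p = (1 + #{R²* ≥ R²}) / (B + 1)`. Tests run over regional
   groupings: all regions, each pair, each single region.
7. **Consensus faces** (`build_consensus`, `consensus_correct`,
   `weighted_consensus_correct`, `retest_after_consensus`). After a fresh
   GPA of the covariate-corrected cohort (a shared frame is required for
   subtraction), each region's member mean is its consensus face. Consensus
   correction is `face - consensus(region) + grand mean`; the weighted
   variant substitutes the admixture-weighted blend of consensus faces and
   reduces exactly to the indicator form when a Q row is degenerate. The
   permutation tests are re-run afterwards to ask which genetic PCs still
   explain facial variation.
8. **Effect maps** (`vertex_normals`, `normal_displacement`,
   `angle_difference`, `max_ancestry_shift`, `compare_correction_methods`).
   Per-landmark summaries: the signed component of a displacement along the
   base face's area-weighted vertex normals (outward positive); the angle in
   degrees between two displacement fields (0 when either vector is shorter
   than `eps = 1e-9`); and the per-landmark maximum, over individuals, of
   the distance moved by ancestry correction.

`run_genetic_pc_route()` and `run_consensus_route()` chain these stages from
one `pipeline_config()`; both routes consume the identical
covariate-corrected cohort.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_per_region` | 186 | individuals | balanced regional subsample size of the emulated protocol |
| `k_ancestry_pcs` | 4 | — | standard width of genetic-PC ancestry correction |
| `k_visual_pcs` | 20 | — | PCs removed for the visualization base face |
| `var_threshold` | 0.96 | fraction | shape-PCA variance retained before testing |
| `B` | 10000 | permutations | null resolution ≈ 1e-4 |
| `exaggeration` | 4 / 8 | — | export-only scaling of regional / single-PC effects |
| `gpa tol` | 1e-8 | shape units | mean-change convergence criterion |
| `angle eps` | 1e-9 | length units | direction undefined below this displacement |

PLSR component counts are not part of the emulated protocol, so
`n_components` defaults to the number of predictors, which makes the fit
coincide with ordinary least squares on full-rank designs — deterministic
and checkable against the normal equations. Fewer components remain
available for regularized fits.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a four-region
cohort on a face-like synthetic template (`make_template`): a smooth convex
height field over a grid, bilaterally symmetric about x = 0, with a
consistent triangulation and an involutive landmark pairing. Template
`extent` defaults to 100 units — think millimetres for a face-sized object.

Each individual is `template + regional deformation + covariate effects +
individual low-rank modes + landmark noise`:

* **Regional deformations** are sums of Gaussian bumps (smooth, localized,
  symmetrized), *projected onto the Procrustes tangent space* at the
  template and centered across regions. The projection matters: a shape-only
  analysis cannot recover translation, rotation or size components of an
  injected field, and the emulated study's regional groups did not differ in
  centroid size — so the generator injects pure shape change. Peak amplitude
  `region_effect_scale = 2` units against landmark noise of
  `noise_sd = 0.5` units, a between/within ratio at which the leading PCs
  are clearly but not trivially significant at n = 186 per region.
* **Covariates**: sex and camera ±1, age ~ U(18, 65), height ~ N(170, 10),
  weight ~ N(75, 15); each drives a smooth field with a configurable
  amplitude.
* **Genetic PCs**: score = per-region mean loading + standard normal noise.
  Default loadings mirror the qualitative European structure: PC1 contrasts
  South against North/West, PC2 is an East–West gradient, PC3 a weak
  North–West contrast, PC4 and PCs 5–20 carry no regional signal.
* **Admixture**: Dirichlet rows with mass 12 on the true region and 1
  elsewhere, so the maximum proportion identifies the true region in ≥ 95%
  of individuals.
* **Reproducibility**: one global seed drives a hierarchical stream with a
  derived substream per individual, so subsetting a cohort never reshuffles
  another individual's draws.

The generator does *not* emulate realistic facial geometry or texture,
genotypes, relatedness, registration error, or missing landmarks. Passing
tests therefore demonstrate the correctness and calibration of the
*procedures* on data with the emulated covariance structure, not performance
on real scans. The within-region/between-region variance ratio is exposed
(`noise_sd`, `mode_scale`, `region_effect_scale`) rather than fixed, since
the emulated study does not report it.

## Numerical choices

* **SIMPLS** extracts components from the SVD of the cross-covariance
  matrix; it is deterministic (no NIPALS inner iteration) and reduces
  components with a warning on rank-deficient designs. At full components it
  reproduces OLS to ~1e-15, which the tests assert against the normal
  equations, and reduced-component fits are cross-checked against an
  independent PLS implementation.
* **Permutation scheme**: re-pairing predictor rows with shapes is the
  default null (exchangeable under the global hypothesis); a
  Freedman–Lane-style residual scheme is available via
  `scheme = "freedman_lane"` and coincides in distribution with row
  permutation when the nuisance model is intercept-only. The add-one
  estimator bounds p away from zero.
* **R² weighting**: the headline statistic weights shape components by their
  eigenvalues, so it reads as a fraction of facial variation; the
  unit-weighted version (matching the normalized scores) is exposed
  alongside. The eigenvalue-weighted value is invariant to the
  normalize-then-back-weight round trip.
* **Ties and degeneracies**: argmax ties break to the first region column;
  even-count medians interpolate; zero-length displacement vectors get angle
  0; zero-variance genetic PCs are dropped from ancestry correction (an
  all-zero PC block makes it a no-op with an identically zero effect field);
  coincident landmarks give centroid size 0 with a warning; rank-deficient
  configurations abort GPA naming the individual.
* **Ground-truth comparison**: recovered effect fields live in Procrustes
  shape space, so `tangent_projection()` removes the seven similarity
  components from both the injected and the recovered field before they are
  correlated.

## Design choices where the protocol was open

* The reflected copy is averaged directly (no re-alignment before
  symmetrization); registered scans share the template frame.
* The consensus GPA runs over the *full* corrected cohort before regional
  averaging, not per region and not on the four means: subtraction of a
  consensus from an individual requires one shared frame.
* Whether PC-combination R² is a joint fit or a sum of marginals was open; a
  joint fit is used.
* Subgroup runs recompute the shape PCA within the subgroup, so each group's
  retained dimension adapts to its own covariance.
* Consensus stores warn below 30 members per region, the size at which
  facial averages are commonly considered robust.

## Problem sizes used for validation

The test suite and acceptance script run the full protocol at reduced scale,
chosen to keep every check comfortably sharp: templates of 100–500 landmarks
(the full 7160-landmark template builds in well under a second and is
validated structurally), 20–60 individuals per region, B = 199–999
permutations for pipeline checks, B = 500 with 200 replicates for type-I
calibration, and 10–50 replicates for Monte-Carlo properties. The type-I
error of the permutation test is verified to sit inside the binomial 95%
band around 0.05, exact-enumeration agreement is verified at n = 6, and the
qualitative consensus result — region-aligned PCs significant before
consensus correction, non-significant after, non-regional PCs unchanged — is
reproduced across 50 simulated cohorts.

## Limitations

* All corrections are linear except the consensus subtraction itself;
  interactions between covariates and ancestry are not modeled.
* The permutation statistic tests global association over the whole face
  (one segment); no per-region-of-the-face segmentation is provided.
* Consensus correction needs every analysis region represented in the store;
  individuals from unrepresented populations can only be handled through the
  weighted correction and only within the span of stored consensus faces.
* p-values across the PCs-by-groups table are reported raw, without
  multiplicity correction, matching the emulated protocol.
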