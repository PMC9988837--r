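# morphancestry

Genetic and phenotypic ancestry correction for dense 3D facial landmark
data.

## What it is for

Facial shape carries a geographic ancestry signal even within a continent.
Studies that associate genetics with facial morphology must remove that
signal from the phenotype, and two traditions exist for doing so:

* **Genetic correction** — regress the landmark coordinates on the leading
  genetic principal components (PCs) and keep the residuals;
* **Phenotypic (consensus) correction** — subtract a regional *consensus
  face* (the mean configuration of a reference group), optionally blended by
  each individual's admixture proportions.

morphancestry implements both on dense quasi-landmark configurations (the
thousands of template-defined surface points produced by non-rigid surface
registration), quantifies each genetic PC's effect on the face, tests it
with permutations, and compares the two corrections landmark by landmark.
It is aimed at researchers in geometric morphometrics and facial genetics
who need a tested, reproducible correction pipeline — and, because real
cohorts of this kind are consent-restricted, it ships a synthetic cohort
generator with known ground truth so every stage is verifiable.

## The statistics at the core

With `n` individuals and `L` landmarks, configurations are symmetrized,
superimposed by generalized Procrustes analysis with scaling (centroid size
`S(X) = sqrt(sum_l ||x_l - x̄||²)` recorded before scaling), and the
`n × 3L` coordinate matrix `Y` is corrected by partial least squares
regression on covariates `X` (sex, age, age², height, weight, centroid
size, camera):

    Y_corrected = Y − X̃ B̂ + ȳ          (residuals plus the mean shape)

Ancestry correction repeats this with the first 4 genetic PCs; the
per-landmark displacement `before − after` is the *genetic facial ancestry
effect*. Significance is assessed by reducing shape to principal components
retaining 96% of variance and permuting the predictor–shape pairing
(B = 10,000): `p = (1 + #{R²* ≥ R²}) / (B + 1)`, where R² is the
eigenvalue-weighted variance of the retained scores explained by the
predictor set. Consensus correction is

    face_corrected = face − Σ_r q_r · consensus_r + grand_mean

with `q` an indicator (assigned region) or an admixture row. Effect maps
report signed displacement along vertex normals, angle differences between
displacement fields, and the per-landmark maximum ancestry shift.

## Worked example

```r
library(morphancestry)

tpl    <- make_template(L = 100, extent = 100)      # synthetic face template
cohort <- generate_cohort(cohort_config(n_per_region = 80, seed = 42), tpl)

cfg <- pipeline_config(B = 999, n_per_region = 40, pc_list = 1:6, seed = 42)
pc  <- run_genetic_pc_route(cohort, cfg)
subset(pc$perm_table, group == "ALL")
#>  group predictors   n m_retained          r2     p
#>    ALL        PC1 160         84 0.069253129 0.001
#>    ALL        PC2 160         84 0.099983307 0.001
#>    ALL        PC3 160         84 0.031911986 0.001
#>    ALL        PC4 160         84 0.004698334 0.734
#>    ALL        PC5 160         84 0.004753157 0.726
#>    ALL        PC6 160         84 0.011956655 0.034
#>    ALL  PC1+2+3+4 160         84 0.189679690 0.001
```

The generator gives PCs 1–3 regional structure and leaves PC4 and higher as
noise; the permutation table recovers exactly that: the region-aligned PCs
explain 3–10% of retained facial variation each (p = 0.001, the add-one
floor at B = 999) while PC4 and PC5 are null. Running the consensus route on
the same covariate-corrected cohort re-tests every PC after consensus
correction:

```r
cons <- run_consensus_route(cohort, cfg, pc_report = pc)
cons$retest[, c("predictors", "p_before", "p_after")]
#>  predictors p_before p_after
#>         PC1    0.001   0.784
#>         PC2    0.001   1.000
#>         PC3    0.001   0.915
#>         PC4    0.734   0.546
#>         PC5    0.726   0.838
#>         PC6    0.034   0.240
max(pc$max_shift)
#> [1] 0.001734  # peak per-landmark ancestry shift, Procrustes shape units
```

Consensus correction absorbs the regional signal completely — the
region-aligned PCs are no longer significant — while the null PCs'
p-values stay unremarkable (PC6's nominal 0.034 before correction is the
kind of chance hit a raw 6-PC scan produces). Per-region displacement and
angle maps comparing the two corrections are in `cons$comparison`, and
`write_scalar_map()` exports any per-landmark map as colourable PLY plus
CSV.

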