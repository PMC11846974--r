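# dbmcov

Structural covariance and trajectory analysis for longitudinal
deformation-based morphometry (DBM) in mouse models of synucleinopathy.

## The problem

In striatal fibril-injection models of Parkinson's disease (hemizygous M83
mice inoculated with alpha-synuclein preformed fibrils, PFF, versus PBS
controls), neurodegeneration unfolds over months and differs between the
sexes. Longitudinal MRI with DBM yields, per scan, a 3-D field of
log-Jacobian determinants — the local volume change needed to warp that
scan onto a common template. `dbmcov` provides the downstream analysis of
those fields for researchers studying whole-brain atrophy patterns:

- **Preprocessing** (`log_transform()`, `gaussian_blur()`,
  `assemble_matrix()`): log-scale Jacobians, Gaussian smoothing specified
  by FWHM in mm, and assembly of an m-voxel x n-scan matrix — sign-inverted
  so atrophy is positive, z-scored per voxel, and shifted by a single
  recorded scalar so the minimum is exactly zero.
- **Orthogonal projective NMF** (`opnmf()`): factorizes the non-negative
  matrix `X ≈ W H` with `H = WᵀX`, where the m x k component matrix `W`
  holds near-orthogonal spatial covariance patterns (each voxel effectively
  belongs to one component) and the k x n weight matrix `H` holds subject
  loadings. Model selection uses split-half **stability analysis**
  (`stability_analysis()`, `select_k()`): components re-estimated on
  disjoint subject halves are matched by optimal-assignment cosine
  similarity, and the granularity is chosen to balance high stability, a
  small reconstruction-error gradient, and low k.
- **Pattern overlap** (`binarize()`, `dice_kappa()`,
  `sex_overlap_report()`): components are binarized by per-voxel ownership
  (argmax) and compared with the Dice similarity coefficient
  `κ = 2a / (2a + b + c)`, quantifying how much sex-specific disease
  patterns overlap the all-subjects pattern.
- **Voxel-wise trajectories** (`fit_voxelwise_lme()`, `fdr_map()`): the
  longitudinal model `volume ~ group * sex * dpi + (1 | subject)` at every
  voxel, fit by a fast shared-eigenstructure profiled-REML engine
  (equivalent to a per-voxel random-intercept REML fit), with
  Benjamini-Hochberg FDR control.
- **Survival and motor behavior** (`encode_task()`, `fit_cox()`,
  `fit_survival()`, `fit_longitudinal_lme()`, `motor_onset_glm()`,
  `bonferroni()`): Cox proportional hazards (Efron ties) for humane-endpoint
  survival and for cutoff-limited motor tasks — wire hang (fall = event,
  success capped at 150 s = censored) and pole test (descent = event,
  failure at 120 s = censored) — plus mixed models for weight/rotarod and a
  motor-onset GLM, with Bonferroni correction across tasks and timepoints.
- **Synthetic cohorts** (`cohort_spec()`, `ground_truth()`,
  `simulate_study()`): a full generative model of such a study — planted
  disjoint smooth atrophy components whose loadings follow
  group x sex x time, hazard-linked attrition, and behavioral latencies
  with the task ceilings/floors — so every stage can be validated against
  known ground truth.

`run_pipeline()` chains all stages on a config and writes CSV/NIfTI
artifacts plus a JSON report; `inst/scripts/dbmcov-pipeline.R` is a thin
command-line wrapper.

## Worked example

```r
library(dbmcov)
library(dplyr)

spec <- cohort_spec(n_per_cell = 8, grid_shape = c(16, 16, 16), seed = 7)
study <- simulate_study(spec)

# cross-sectional decomposition at 90 dpi (absolute Jacobians)
blurred <- lapply(study$images_absolute, gaussian_blur, fwhm_mm = 0.17)
cross <- blurred[vapply(blurred, function(im) im$dpi == 90, logical(1))]
dm <- assemble_matrix(cross, study$mask)
dm
#> <data_matrix> 1328 voxels x 29 scans | absolute | inverted | z-scored | shift 3.513

meta <- left_join(dm$column_meta,
                  distinct(study$cohort, subject_id, sex, group),
                  by = "subject_id")
prof <- stability_analysis(dm, k_list = seq(2, 8, 2), n_splits = 5, seed = 7,
                           strata = paste(meta$group, meta$sex))
as.data.frame(prof)
#>   k stability error error_gradient
#> 1 2     0.654   114             NA
#> 2 4     0.500   109         -4.831
#> 3 6     0.349   108         -1.324
#> 4 8     0.283   107         -0.963
select_k(prof)
#> [1] 2

fit <- opnmf(dm, select_k(prof))
subject_weight_glm(fit, 1, meta)$cohens_d
#>   contrast                d variant
#> 1 group_PFF_minus_PBS 0.937 pooled
#> 2 sex_M_minus_F       0.198 pooled
```

The stability profile reads as in the study design: granularities beyond
the planted structure reconstruct barely better (small `error_gradient`)
but are less reproducible across subject splits, so the smallest stable
granularity is selected. The subject-weight GLM then asks whether loading
on a spatial pattern separates the injection groups — here the first
component separates PFF from PBS with a pooled Cohen's d of 0.94.

Behavioral inference with censoring-aware encoding (wire hang at 120 dpi;
the event is a fall before the 150 s cap):

```r
rec <- encode_task(filter(study$behavior, dpi == 120), "wirehang")
cox <- fit_cox(rec)
cox$coefficients
#>   term          estimate hazard_ratio std.error statistic       p.value
#> 1 groupPFF         3.43        30.9      0.589      5.82  0.00000000576
#> 2 sexM             1.38         3.97     0.800      1.72  0.0848
#> 3 trial           -0.113        0.893    0.170     -0.663 0.507
#> 4 weight_g        -0.131        0.877    0.0874    -1.50  0.133
#> 5 groupPFF:sexM   -0.435        0.647    0.640     -0.679 0.497
bonferroni(0.00000000576, m = 8)$significant
#> [1] TRUE
```

Fibril-injected mice fall from the wire far sooner (hazard ratio 30.9 for
falling, surviving Bonferroni correction across 2 tasks x 4 timepoints),
while trial number and body weight contribute little — the synthetic
cohort plants exactly this structure.

Voxel-wise trajectory mapping on the relative-flavor Jacobians:

```r
rel <- lapply(study$images_relative, gaussian_blur, fwhm_mm = 0.17)
dmr <- assemble_matrix(rel, study$mask, zscore = FALSE)
vfit <- fit_voxelwise_lme(dmr, left_join(dmr$column_meta,
          distinct(study$cohort, subject_id, sex, group), by = "subject_id"))
mp <- fdr_map(vfit, "groupPFF:dpi", q_level = 0.01)
sum(mp$significant)
#> [1] 275
```

275 of 1328 in-mask voxels show a group-by-time volume trajectory
difference at 1% FDR — the planted atrophy components.

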