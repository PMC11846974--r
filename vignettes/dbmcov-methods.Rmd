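---
title: "Models and methods in dbmcov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in dbmcov}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbmcov)
```

`dbmcov` analyzes longitudinal deformation-based morphometry (DBM) of
mouse brains: per-scan log-Jacobian determinant volumes, a cohort table
with survival and motor-onset information, and per-trial motor-task
latencies. This vignette explains the models the package fits, the
numerical choices behind them, and what the synthetic cohort generator
does and does not emulate.

## From Jacobians to an analysis matrix

A DBM pipeline upstream of this package registers every scan to a common
template; the Jacobian determinant of the deformation measures local
volume change. Two flavors exist: *relative* Jacobians capture only the
nonlinear (focal) deformations and feed the longitudinal voxel-wise
models; *absolute* Jacobians additionally carry residual global size
differences and feed the cross-sectional covariance decomposition.

`log_transform()` takes natural logs (contraction negative, expansion
positive). `gaussian_blur()` smooths with a separable Gaussian specified
by its full width at half maximum in millimetres
(`sigma = fwhm / (2 * sqrt(2 * log(2)))`, converted to voxel units per
axis). Boundaries are handled by symmetric reflection, which conserves
the volume mean; kernels narrower than a tenth of a voxel are a no-op
with a warning. At the study's imaging resolution a FWHM of ~0.085 mm is
typical; the examples here use coarser grids and scale the kernel
accordingly.

`assemble_matrix()` builds the m-voxel x n-scan matrix the factorization
consumes. Three conventions are deliberate, because the field's usage
leaves them open:

- **Inversion** is multiplication by -1 of the log-Jacobian, so atrophy
  (contraction) loads positively in a non-negative factorization.
- **Non-negativity** is achieved by one global scalar shift of the
  z-scored matrix (minimum maps to exactly 0). A single shift preserves
  all variance structure, unlike clipping; the shift is recorded in
  `zshift` and `unassemble_matrix()` undoes the whole normalization.
- **Z-scoring** happens per voxel across scans, after inversion and
  before the shift. Zero-variance voxels are dropped with a count; the
  voxel-to-grid map is kept (`voxel_index`, R column-major linear
  indices) so any per-voxel result can be written back as a volume.

## Orthogonal projective NMF

The decomposition approximates the non-negative matrix `X` by `W H` with
`H = WᵀX` (projective form), `W >= 0` of size m x k. Minimizing
`||X - W WᵀX||_F` under non-negativity drives `WᵀW` toward a diagonal
matrix, so components are near-orthogonal: each voxel effectively belongs
to one spatial pattern, while a subject can load on many.

Numerically, `opnmf()` uses the symmetric multiplicative update

```
W <- W * (2 XXᵀW) / (W WᵀXXᵀW + XXᵀW WᵀW)
```

computed through k x k intermediates (never forming the m x m matrix
`XXᵀ`), with three stabilizers:

1. **Optimal global rescale.** The projective objective is
   scale-sensitive; after each update `W` is rescaled by the closed-form
   scalar minimizing the error, which prevents the scale oscillation the
   raw update exhibits.
2. **Monotone guard with damped retries.** If a step would increase the
   error, the exponent of the multiplicative ratio is halved up to four
   times; if no damped step descends, the phase stops. The recorded error
   trace is therefore nonincreasing by construction.
3. **Guarded partition polish.** Multiplicative updates approach the fixed
   point at a slow O(1/t) rate. Periodically (and at convergence) the
   package solves the objective exactly *given the current ownership
   partition*: on each component's argmax-support block the optimal column
   is the block's dominant left singular vector. The polished `W` is
   accepted only if it lowers the error. On exactly low-rank orthogonal
   inputs this lands machine-precision solutions; on noisy data it either
   helps or is rejected.

Initialization is deterministic non-negative double SVD (NNDSVD) by
default, so repeated runs are bit-identical; a seeded uniform
initialization is available. Convergence is declared at a relative error
change below `tol = 1e-5` (up to `max_iter = 10000` updates). Output
columns of `W` have unit Euclidean norm with the scale carried into `H`
(the product `W H` is unchanged); per-iteration column renormalization
was rejected because it breaks the monotonicity of the error trace.
Components are ordered by loading energy.

## Stability analysis and choosing k

`stability_analysis()` evaluates granularities (default k = 2..20 in
steps of 2, per the study design) by two measures:

- **Stability**: subjects are split into two disjoint halves (5 splits by
  default, stratified by sex-by-group cells when provided — the natural
  stratification for this design), the factorization runs on each half,
  and the two component sets are compared by cosine similarity under
  optimal one-to-one matching (a hand-rolled O(k³) Hungarian solver,
  cross-checked against brute-force enumeration in the tests). The mean
  matched cosine over splits is the stability at k.
- **Reconstruction-error gradient**: the change in full-matrix Frobenius
  error from the previous granularity (the profile stores this backward
  difference; the first entry is `NA`).

`select_k()` encodes "high stability, low gradient, low k" as: the
smallest k with stability within 90% of the maximum whose *outgoing*
gradient (the error change of the step leaving k) is at most the median
absolute gradient. The outgoing direction matters: at the true
granularity the step *onto* it still gains a lot of accuracy, but the
step *beyond* it gains little, which is exactly the plateau the rule
should detect. The full profile is always returned so any other rule can
be applied (`rule` argument).

## Binarized patterns and Dice overlap

`binarize()` assigns each voxel to the component with the largest weight
(ties toward the lowest index, counted; all-zero rows excluded and
counted), consistent with the orthogonal model's voxel exclusivity — no
arbitrary threshold is introduced. `dice_kappa()` computes
`κ = 2a / (2a + b + c)` on voxel counts; two empty patterns define
`κ = 0`, and an empty pattern against a nonempty one warns.
`sex_overlap_report()` identifies, per decomposition (all subjects, males
only, females only), the component whose subject-weight GLM group effect
is most significant, and reports the pairwise κ between the three
binarized patterns — a proxy for which sex drives the pooled pattern.

## Voxel-wise mixed models

The longitudinal model at each voxel is
`volume ~ group * sex * dpi + (1 | subject)`. Because every voxel shares
the design, `fit_voxelwise_lme()` profiles the REML criterion over the
ratio of subject to residual variance on a shared eigendecomposition of
the random-intercept structure: for each candidate ratio the criterion
for *all* voxels costs one small QR, so the grid (0 plus 49 log-spaced
values over 1e-3..1e3, locally refined) prices thousands of voxels in
fractions of a second. The per-voxel `lmer` fit is the oracle in the test
suite; estimates agree to ~1e-4 and standard errors to ~1%.

Denominator degrees of freedom follow the classical between-within rule:
terms varying within subject (those involving time) are tested on
`n_obs - n_subjects - p_within` df, subject-constant terms on
`n_subjects - p_between`. In this balanced-by-design setting the
within-subject df coincide with Satterthwaite's to a decimal, while
between-subject df are slightly conservative; the rule is exact,
deterministic and costs nothing per voxel, which is what a
mass-univariate engine needs. Voxels with degenerate response (zero
residual variance) get `NA` statistics and are counted, never silently
dropped; they are excluded from FDR with the count reported.

`fdr_correct()` is Benjamini-Hochberg step-up (monotone q-values;
significance at `q <= q_level`, study-scale default 1%). `cohens_d()`
carries an explicit variant tag: `"pooled"` (unbiased pooled SD, the
default) or `"population"` (maximum-likelihood pooling) — published d
values are not comparable across variants, so the tag is mandatory in
reports.

## Survival and motor behavior

`encode_task()` translates task latencies into survival records under the
tasks' cutoff semantics. The modeled event follows each task's direction
of impairment: for the wire hang the event is a *fall* before the success
cap (a capped trial is censored); for the pole test the event is a
*successful descent* (failures, recorded at the 120 s maximum or at a
partial-fall time, are censored). Latencies above a cap violate the
generator contract and error. The wire-hang cap is a parameter defaulting
to 150 s — the recorded maximum in this paradigm, even though the task is
often described with a 3-minute cutoff phrase.

`fit_cox()` wraps `survival::coxph` with Efron tie handling (latency caps
produce ties only among censored records, but dpi ties occur in the
survival model, where Efron is the accurate choice). Trials enter as
independent records with trial number and body weight as covariates — the
stated covariate set — rather than being averaged. Monotone likelihood
(separation) is converted into an informative error suggesting
penalization; at realistic study sizes the humane-endpoint model can be
separated simply because control cells have no events, and
`run_pipeline()` records that outcome instead of failing.
`fit_longitudinal_lme()` reuses the voxel-wise engine on a single series
(rotarod latencies are first averaged across the three trials per
timepoint) and exposes a quadratic time coding for inverted-U weight
trajectories. `bonferroni()` uses strict inequality at the
`alpha / m` boundary with `m = 8` by default (two cutoff-limited tasks,
four timepoints).

## What the synthetic cohort emulates

`cohort_spec()` fixes the design: balanced sex-by-group cells (default 15
per cell, ~30 mice per injection group at baseline), scans at -7, 30, 90
and 120 days post-injection, censoring at 130 dpi. The ground truth
plants:

- **Spatial components**: Gaussian-smoothed ellipsoid indicators with
  pairwise disjoint supports inside an ellipsoidal brain mask, mirroring
  the voxel exclusivity of the orthogonal factorization so recovery is
  well-posed. Placement retries shrink the target blob; a mask too small
  for the requested number of components errors explicitly.
- **Loadings**: per-component linear coefficients on intercept, group,
  sex, dpi, group x dpi and group x sex x dpi. The default structure puts
  a male-biased group-by-time effect on component 1, a sex-shared one on
  component 2, and normative structure (aging drift, sex dimorphism) on
  the rest. Log-Jacobians are `-(loadings x components) + noise`
  (`noise_sd = 0.05`); the absolute flavor adds a per-subject global
  size offset (SD 0.02).
- **Survival**: exponential proportional hazards with log-HR coefficients
  for group, sex and their interaction. Defaults
  (baseline 1e-4/day, group 1.4, interaction 1.9) put roughly 30% of male
  PFF mice past the humane endpoint before 130 dpi and very few others —
  the sex asymmetry the study reports. Attrition is hazard-linked only:
  the deliberate diversion of animals to terminal experiments is not
  emulated, so late-timepoint sample sizes shrink less than in the real
  design.
- **Behavior**: latencies are log-normal by default (strictly positive,
  right-skewed), location-shifted by group x days-since-injection, with
  the pole test carrying an additional outright-failure probability on the
  logit scale. Each task also accepts an exponential proportional-hazards
  family, which gives the generator a well-defined planted hazard ratio
  for recovery tests. Rotarod has no cap; wire-hang and pole trials are
  clipped and scored by the rules above.

Not emulated: raw image formation, registration error, scanner artifacts,
spatially correlated noise (voxel noise is i.i.d.; blur induces local
correlation afterwards), within-session trial-order effects, and the
terminal-experiment siphoning. Passing tests therefore demonstrate the
statistical machinery under a faithful *effect structure*, not robustness
to registration failure or structured noise.

## Test and validation scale

The validation suite runs the whole pipeline at reduced sizes chosen to
keep the statistical questions honest while staying cheap: factorization
oracles at m <= 200 voxels, stability selection at m = 300, n = 48 with
k up to 12 and ten seeded replicates, FDR calibration with 1000 voxels,
40 subjects and 200 replicate cohorts, hazard-ratio recovery over 100
simulated task datasets, and end-to-end pipeline runs on 14^3 grids.
Determinism is asserted byte-for-byte on the pipeline report under a
fixed configuration.

## Known limitations

- The random-effects structure is a single random intercept; random
  slopes over time are not supported (nor used in this design's models).
- Between-subject df are mildly conservative relative to Satterthwaite.
- The Cox models have no frailty term for repeated trials; trial number
  as a fixed covariate follows the stated modeling choice, but
  within-mouse correlation of trials is otherwise ignored.
- `select_k` implements one defensible reading of "high stability, low
  gradient, low k"; the profile is returned so alternatives can be
  plugged in.
- Dice overlap values depend on the binarization convention (ownership
  argmax); no permutation inference on κ is provided.
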