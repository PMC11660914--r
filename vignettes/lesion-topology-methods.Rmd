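---
title: "Methods: lesion topology, atlas overlap and permutation inference in gbmtopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion topology, atlas overlap and permutation inference in gbmtopo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmtopo)
```

# Scope and data model

`gbmtopo` analyses cohorts of binary glioblastoma lesion masks that have
already been normalized to a common template grid. Image preprocessing
(bias-field correction, skull stripping, registration, segmentation) is
deliberately out of scope: the package's unit of analysis is the voxel of a
shared `ImageGrid`, and every statistic downstream is a function of voxel
counts. For that reason the package *refuses* grid mismatches instead of
resampling: nearest-neighbour resampling changes voxel counts, which are the
unit of every overlap fraction, network ratio and voxel-wise test. An
explicit `resampleNearest()` exists for users who accept that cost.

Each subject contributes a tumour *core* mask (enhancing and non-enhancing
tumour plus necrosis), an *oedema* mask, and their union (*global*). Overlap
statistics are computed on core masks; the other compartments can be passed
explicitly. Masks are binarized at a fixed 0.5 threshold on read — manual
segmentations are already binary, so the rule only guards against
interpolated inputs.

# Overlap measures

Three measures, chosen to match how the lesion-location literature reports
involvement:

- **Lobar involvement** is binary per lobe, requiring at least 250
  overlapping voxels. The threshold is inclusive (≥ 250) and configurable;
  250 voxels is the conventional guard against counting a lobe as involved
  on the strength of a sliver of partial-volume overlap. When synthetic
  templates smaller than a standard 1 mm/2 mm brain are used, the threshold
  should be scaled with the voxel volume.
- **Compartment fractions**: for cortex, white matter and deep grey nuclei,
  the fraction of lesion voxels inside the compartment. Fractions need not
  sum to 1, because lesion voxels may fall outside all three compartments
  (e.g. ventricles in a coarse parcellation). An empty lesion yields
  undefined (`NA`) fractions, never 0 — a 0 would silently claim "no
  involvement" where there is no lesion to measure.
- **Within-tissue network ratios**: lesion voxels in a network divided by
  lesion voxels in the union of all networks of the same family (grey- or
  white-matter). Background is excluded from the denominator, so defined
  ratios sum to exactly 1 and are compositional. A lesion missing every
  network of a family yields all-`NA` ratios; such subjects are dropped
  listwise from network-level tests, with the count logged. This handling is
  a package decision — dropping is transparent and conservative, and the
  logged count lets the analyst judge the cost.

# Cohort statistics

Methylation status is dichotomized at **≥ 8%** (inclusive), the
pyrosequencing cutoff in routine diagnostic use. Median splits of the
percentage send values equal to the median to the *low* group; the
literature rarely states its tie rule, so the package picks one
deterministically and reports the number of ties.

The 2×2 χ² is the **uncorrected** Pearson statistic. This is a deliberate
choice: on the reference hemisphere-by-status table reconstructable from
group sizes and proportions, the continuity-corrected statistic (≈ 3.3,
p ≈ 0.07) cannot reproduce the reference χ² = 4.1, p = 0.042, while the
uncorrected one does. t-tests default to the pooled-variance (Student) form,
with Welch available by flag. Partial correlations use the first-order
closed form and are verified in the tests against residual-regression
correlations to 1e-10.

The repeated-measures test of network overlap profiles uses the
**multivariate approach**: the k within-subject measures are reduced to
k − 1 orthonormal difference contrasts, and equality of condition means is
tested by Wilks' Λ = det(E)/det(E+H), converted to an exact F with
(k − 1, n − k + 1) degrees of freedom (the hypothesis has one degree of
freedom, so the F is exact, not an approximation). The multivariate approach
makes no sphericity assumption — appropriate for compositional ratios, whose
covariance is constrained. With a between-subject covariate (methylation
status coded 0/1), the package additionally tests the condition ×
covariate interaction by Wilks' Λ on the contrast scores regressed on the
covariate, with (k − 1, n − k) df. Whether status should enter as a factor
or a covariate is genuinely open in this design; the interaction-on-contrast-
scores formulation is implemented because it directly operationalizes "does
the distribution profile across networks depend on status", and it is
flagged as an interpretation in the results. Bonferroni correction always
carries an explicit family size (e.g. the six pairwise comparisons among the
four status-by-side categories give an adjusted alpha of 0.05/6 ≈ 0.008).

# Voxel-wise inference

The voxel-wise stage regresses the per-voxel 0/1 lesion indicator on
[intercept, predictor, nuisance...] by OLS and tests the predictor
coefficient. With a binary predictor and no nuisance this is exactly the
per-voxel two-sample pooled t; with a continuous predictor it is the Pearson
t-transform; with nuisance it equals the partial-correlation t — all three
reductions are asserted in the tests.

Voxels enter the analysis when lesioned in at least 2 subjects (the same
threshold as the frequency-map display rule; configurable). Family-wise
error is controlled by the **max-statistic permutation method**: the null
distribution of the maximum |t| over the analysis mask is built from
permutations, and p_FWE(v) = (1 + #{max ≥ |t_obs(v)|})/(n_perm + 1). The
+1/+1 convention includes the observed statistic in the null, so p > 0
always and the test is exact-level. When the permutation space is no larger
than the requested number of permutations (binary predictors with small
groups, or n ≤ 8 otherwise) it is enumerated exhaustively and the
denominator becomes the space size. With nuisance covariates, labels cannot
be permuted naively; the **Freedman–Lane** scheme permutes the residuals of
the reduced (nuisance-only) model and adds back the nuisance fit, the
standard choice in randomise-style lesion mapping. A simple-permutation flag
exists for comparison. Two-tailed max-|t| is the default, since both
directions of a location effect are of interest.

Lesion flipping pools left- and right-sided lesions to raise the effective
lesion count per voxel: `mirror` reflects every mask about the mid-sagittal
voxel plane, while `unify_left`/`unify_right` reflect only the masks whose
centre of mass lies in the opposite hemisphere. The left-right axis is read
from the affine's dominant world-x direction; a centre of mass exactly on
the midline is treated as already unified (deterministic, logged). Both
modes are provided because published flipped-lesion analyses rarely state
which convention they used; neither is claimed as anyone's.

# The synthetic cohort generator

The generator exists so the entire pipeline can be exercised, calibrated and
regression-tested without any imaging data. Its defaults are the study
conditions the package targets: 93 subjects, 42 methylated, 41 with a
quantified methylation percentage of mean 33.9, SD 18.3, floored at 8 for
the methylated subset; core volumes 43.2 ± 29.3 mL and oedema 54.8 ± 43.4 mL
(truncated normals); and a planted correlation of +0.36 between methylation
percentage and the realized cortical overlap fraction.

The template is a mirror-symmetric ellipsoid on a 64³ grid of 2 mm
isotropic voxels — large enough that cortex ribbon, white-matter interior,
two bilateral deep-grey nucleus pairs, five lobar sectors, seven grey-matter
network parcels and four white-matter network parcels are all distinct,
small enough that a full cohort generates in seconds. Lesions are grown by
stochastic 6-connected Eden-type region growing (compiled kernel, driven by
R's RNG so everything is reproducible from one seed) from a seed voxel
sampled from a per-subject tissue-class mixture; the oedema is grown
outward from the core surface as a disjoint shell. Cores are single
connected components by construction and reach their target volume within
±10%.

The correlation is planted *conditionally on geometry*: lesions are grown
first, each subject's cortical fraction is measured, and the methylation
percentage is generated as a linear function of that fraction plus Gaussian
noise calibrated through sd_noise = sd_signal·√(1/r² − 1), so the
pre-clipping correlation equals the planted value by construction. Clipping
to [8, 100] attenuates it slightly; the post-clipping achieved correlation
is measured and stored in `plantInfo`, never silently corrected. The
negative correlation with deep grey involvement is *not* independently
planted — it emerges from the compositional cortex/deep trade-off — and is
verified empirically. The unmethylated group's lesions are drawn from the
same spatial family (no planted group difference), so categorical group
contrasts are null by construction, and `generateNullCohort()` additionally
permutes the methylation columns against the lesions for permutation
calibration with an identical lesion set.

What the generator does **not** emulate: real lesion morphology (infiltrative
margins, necrotic cavities), spatial preference maps of real GBM (e.g.
periventricular clustering), registration error, or segmentation noise.
Passing tests therefore demonstrate the correctness and calibration of the
*statistical machinery* under the stated generative assumptions, not the
biological conclusions one would draw on real data.

# Numerical and design choices

- Grid tolerance for affine agreement: 1e-4 mm absolute, loose enough for
  round-trip float error, tight enough to catch any real mismatch.
- Binarization threshold 0.5, fixed.
- Wilks' Λ requires a nonsingular error SSCP; constant contrast scores (all
  subjects identical across conditions) raise an error rather than return a
  degenerate statistic, and the pipeline logs and skips families where
  n ≤ k − 1.
- Zero pooled variance in the t-test returns t = 0, p = 1 when the means
  agree and errors otherwise.
- The pipeline derives per-stage seeds from the global seed by a stable
  string hash of the stage name, so stages can be rerun in isolation and
  byte-identical outputs are guaranteed for identical config + seed.
- Problem sizes used by the validation suites: parameter recovery runs 100
  default-size cohorts; permutation calibration runs 200 null cohorts on a
  reduced 32³ / 4 mm template with 200 permutations each — at that scale the
  expected max-statistic null is well resolved while a full calibration run
  stays in the minutes range.

# Known limitations

- The voxel-wise GLM treats the binary lesion indicator as a continuous
  response, as classical lesion-mapping GLM tools do; the permutation
  inference makes this distribution-free at the FWE level, but per-voxel
  uncorrected p-values are parametric and approximate.
- Network ratio compositionality means the k ratios are linearly dependent
  across the family; the contrast-score reduction absorbs this, but
  per-network univariate tests on ratios should be interpreted with the
  usual compositional-data caveats.
- The lobar 250-voxel rule is calibrated for ~1–2 mm template resolutions
  and must be rescaled for coarser synthetic grids.
- `unify_*` flipping assumes the template itself is mirror-symmetric about
  the mid-sagittal voxel plane; the synthetic template is symmetric by
  construction, and real templates should be checked before pooling.
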