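# gbmtopo

Lesion topology and MGMT promoter methylation analysis for glioblastoma
cohorts.

## The problem

Whether glioblastoma (GBM) location relates to MGMT promoter methylation —
the main predictive epigenetic marker for alkylating chemotherapy response —
has been studied mostly with coarse, categorical designs and conflicting
results. `gbmtopo` implements the full analysis stack needed to ask the
question quantitatively in a normalized template space, for researchers with
cohorts of manually segmented lesion masks (tumour core and oedema, binary
NIfTI volumes on a shared grid) and per-patient pyrosequencing methylation
percentages:

- **Atlas overlap quantification** — per-subject overlap of the tumour core
  with lobes (a lobe counts as involved at ≥ 250 overlapping voxels), with
  tissue compartments (cortex / white matter / deep grey nuclei: overlap
  volume in mL and fraction of the lesion), and with grey- and white-matter
  functional network parcellations, where the measure is the within-tissue
  ratio: voxels in a network divided by voxels in all networks of the same
  tissue, so defined ratios sum to 1. Group lesion frequency maps with the
  usual "show voxels covered by ≥ 2 lesions" display rule.
- **Cohort statistics** — methylation dichotomization at the ≥ 8% cutoff,
  median splits (ties to the low group), uncorrected Pearson χ² on 2×2
  tables, pooled-variance t-tests, Pearson correlations, first-order partial
  correlations r(x,y·z) = (r_xy − r_xz r_yz)/√((1−r_xz²)(1−r_yz²)) for
  volume correction, repeated-measures tests of network overlap profiles via
  Wilks' Λ = det(E)/det(E+H) with its exact F transform, and Bonferroni
  correction with explicit family sizes.
- **Voxel-wise lesion mapping** — mass-univariate GLM of the per-voxel 0/1
  lesion indicator on a predictor (group, methylation %) plus optional
  nuisance covariates, with max-statistic permutation FWE correction
  (p_FWE(v) = (1 + #{max_perm ≥ |t_obs(v)|})/(n_perm + 1)), Freedman–Lane
  permutation of reduced-model residuals when nuisance covariates are
  present, exact enumeration when the permutation space is small, and
  hemispheric lesion flipping (mirror or unify-to-one-side) to pool
  left- and right-sided lesions.
- **Synthetic cohorts** — a seed-reproducible generator (template brain,
  parcellations, stochastic region-grown core + oedema masks, molecular
  data) whose defaults emulate a 93-subject cohort (42 methylated, 41
  quantified, methylation 33.9 ± 18.3%, core volume 43.2 ± 29.3 mL, oedema
  54.8 ± 43.4 mL) with a planted correlation of +0.36 between methylation
  percentage and cortical overlap fraction, so that every pipeline stage is
  testable end to end without any data download.

## Worked example

```r
library(gbmtopo)

ch <- generateCohort(syntheticCohortSpec(seed = 8))
man <- ch$manifest

# quantified methylated subset: methylation % vs cortical overlap fraction
q <- which(man$methylation_status == "methylated" & !is.na(man$methylation_pct))
frac <- overlapTable(ch$masks$core[q], ch$template$tissue, "fraction")
pearsonR(man$methylation_pct[q], frac$cortex)
#>        test  n statistic df1 df2   p_value p_corrected family_size
#> 1 pearson_r 41 0.3535714  39  NA 0.0233444          NA          NA

# the same association, corrected for tumour core volume
partialR(man$methylation_pct[q], frac$cortex, man$core_volume[q])
#>        test  n statistic df1 df2    p_value p_corrected family_size
#> 1 partial_r 41  0.382131  38  NA 0.01496124          NA          NA
```

The planted cortical association is recovered (r = 0.354 here, planted
population value 0.36, n = 41), survives volume correction, and the
correlation with deep grey matter involvement comes out negative
(`ch$plantInfo$achieved_r_deep` is −0.368 for this seed), mirroring the
compositional trade-off the generator encodes. A full run —

```r
out <- runFullAnalysis(ch, "results-run", nPerm = 1000, seed = 8)
```

— writes tidy TSV test results, per-atlas overlap tables, NIfTI frequency
and statistical maps, and a run log with every seed, threshold and family
size. A thin CLI with `simulate` / `validate` / `overlap` / `stats` /
`voxelwise` / `all` subcommands is installed under `exec/gbmtopo`.

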