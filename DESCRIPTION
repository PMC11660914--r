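Package: gbmtopo
Title: Lesion Topology and MGMT Promoter Methylation Analysis for Glioblastoma Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for relating glioblastoma lesion location to MGMT promoter
    methylation in a normalized template space. Provides NIfTI lesion-mask and
    label-atlas input/output with strict grid checking, atlas overlap
    quantification (lobar involvement, tissue-compartment fractions,
    within-tissue functional-network ratios, group frequency maps),
    cohort-level statistics (methylation dichotomization, chi-square and t
    tests, Pearson and partial correlations, repeated-measures Wilks' lambda
    tests, Bonferroni correction), voxel-wise lesion mapping with
    max-statistic permutation family-wise error correction (including
    Freedman-Lane nuisance handling and hemispheric lesion flipping), and a
    synthetic cohort generator with planted location-methylation effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
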