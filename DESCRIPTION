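Package: vmti
Title: Visuo-Motor Temporal Integration Analysis for Stroke Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for delayed-visual-feedback detection studies
    of visuo-motor temporal integration after left hemispheric stroke.
    Fits two-parameter logistic psychometric functions to per-delay
    detection probabilities to estimate the delay detection threshold and
    curve steepness, runs the group-level statistical battery
    (tie-corrected Kruskal-Wallis, chi-square, split-plot mixed ANOVA with
    Tukey-Kramer and Bonferroni-corrected post hocs, exact small-sample
    rank tests, Spearman correlations), and performs lesion analyses on
    binary NIfTI masks: overlap maps, percentage subtraction maps, and
    voxel-based lesion-symptom mapping with per-voxel Brunner-Munzel tests
    under Benjamini-Hochberg false discovery rate control. A synthetic
    cohort generator produces patients, trial-level Bernoulli responses,
    and lesion volumes with the coupling structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
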