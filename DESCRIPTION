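Package: lesionmapr
Title: Voxel-Wise Lesion Localization Analysis for Multiple Sclerosis Cohorts
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-level analysis of binary white-matter lesion
    masks registered to a common template space. Builds per-voxel lesion
    prevalence maps (3-D lesion histograms), quantifies registration quality
    with the goodness-of-lesion-spatial-registration (GLSR) statistic, measures
    lesion-pattern atypicality with the location-discrepancy index (LDI), and
    fits a hierarchy of voxel-wise regressions of a disability score (EDSS) on
    lesion presence with confounder adjustment, Bonferroni and
    Benjamini-Hochberg multiplicity correction, sample-size extrapolation and a
    proportional-odds ordinal-outcome variant. Includes a synthetic lesion
    cohort generator with controllable periventricular clustering,
    disability linkage and misregistration perturbations, plus minimal NIfTI-1
    input/output so the whole pipeline runs without external imaging stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
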