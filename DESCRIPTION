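Package: petgeom
Title: Hotspot Geometry Radiomics and Outcome Modelling for FDG PET
Version: 0.1.0
Authors@R: person("petgeom", "maintainers", email = "petgeom@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying intratumoral metabolic heterogeneity on
    FDG PET volumes and relating it to treatment outcome. Implements
    adaptive-threshold (Nestle) lesion segmentation, the conventional SUV
    features (SUVmax, SUVpeak, MTV, TLG), normalized hotspot-to-centroid
    (NHOC) and hotspot-to-perimeter (NHOP) distances, and the downstream
    cohort statistics (rank tests, Spearman correlation, ROC with Youden
    cutoffs and DeLong comparisons, logistic regression for pathological
    complete response, Cox and Kaplan-Meier survival analysis). A synthetic
    phantom and cohort generator with known ground truth makes every stage
    testable end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
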