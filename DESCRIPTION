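Package: stenometry
Title: Quantifying Renal Artery Stenosis on 3-D Angiographic Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for measuring renal artery stenosis on 3-D
    computed-tomography and magnetic-resonance angiography volumes: ROI-based
    threshold selection, competing fuzzy-connectedness vessel segmentation,
    centerline extraction, perpendicular cross-section morphometry (minimum
    Feret diameter and area), relative diameter/area reduction with
    bifurcation-aware eligibility rules, per-kidney summarization under the
    First/Tightest/Main approaches, and the evaluation statistics used to
    compare such measurements (Bland-Altman limits of agreement, two-way
    random-effects intraclass correlation, ROC/AUROC with DeLong confidence
    intervals and paired tests). Includes a synthetic phantom and reader-cohort
    generator with analytically known stenosis geometry so every stage is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    generics,
    ggplot2,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
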