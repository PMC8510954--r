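Package: hgpradiomics
Title: CT Radiomics for Histopathological Growth Patterns of Colorectal Liver Metastases
Version: 0.1.0
Authors@R:
    person("HGP", "Radiomics Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A fully testable reimplementation of a CT radiomics pipeline for
    distinguishing desmoplastic from replacement histopathological growth
    patterns (HGP) of colorectal liver metastases. Includes a synthetic cohort
    generator emulating the statistical structure of a multi-observer,
    multi-scanner study (patient-grouped lesions, four segmentation observers
    with calibrated Dice agreement, a CNN-like observer with a miss rate, and
    scanner batch effects); a 564-feature radiomics bank (intensity, shape,
    GLCM, LBP, Gabor, LoG, vesselness, local phase); feature-reliability
    screening by intraclass correlation; empirical-Bayes ComBat batch
    harmonization; a random search over preprocessing+classifier workflows
    with top-k ensembling; and 100x patient-grouped random-split evaluation
    with corrected resampled t-test confidence intervals and fixed-width ROC
    bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
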