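Package: ddrFoci
Title: Scoring of 53BP1 Nuclear Focus Patterns and Dual-Color FISH in Lymphoid Lesions
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies DNA damage response (DDR) activation patterns in
    lymphoid-lesion immunofluorescence images. Segments nuclei from the DAPI
    channel, detects 53BP1 nuclear foci with a multiscale Laplacian-of-Gaussian
    blob detector, classifies each nucleus into one of five expression
    patterns (stable, low DDR, high DDR, large focus, diffuse), and computes
    the per-case abnormal fraction used to separate benign lymphoid lesions
    from B-cell lymphomas. Also calls t(11;18)(q21;q21) fusion and trisomy
    18q21 genotypes from dual-color interphase FISH images, and provides the
    diagnostic statistical layer: ROC/AUC with DeLong confidence intervals and
    Youden-index cutoffs, exact Wilcoxon rank-sum tests with mid-rank tie
    handling, Spearman correlation, ordinal trend tests, and a configurable
    decision-flow rule engine. A synthetic-data module generates cohorts and
    rendered multichannel images with per-nucleus ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
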