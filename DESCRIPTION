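Package: climbr
Title: Automated Annotation of Home-Cage Climbing and Circadian Activity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-by-frame recognition of cage-lid climbing in home-cage video
    of laboratory mice, and downstream circadian analysis of the resulting
    ethograms. Motion in a region of interest adjacent to the wire cage lid is
    summarised per video frame by a local trinary pattern (LTP) descriptor, a
    linear support vector machine classifies each frame as climbing or
    non-climbing, and a temporal voting window smooths the frame labels.
    Classifier and voting parameters are selected by leave-one-segment-out
    cross-validation against multi-annotator consensus gold standards.
    Downstream tools bin cage activity into zeitgeber time, summarise the
    30-minute windows flanking the light transitions, and fit Box-Cox
    transformed linear mixed-effects models with estimated-marginal-means
    contrasts under Benjamini-Hochberg correction. Seeded generators for
    synthetic climbing video, imperfect annotators and structured cage
    activity provide a fully reproducible test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Rcpp,
    MASS,
    lme4,
    lmerTest,
    emmeans,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    png,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
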