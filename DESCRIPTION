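Package: curvemeter
Title: Automated Curvature-Angle Measurement from 2D Shaft Silhouettes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for quantifying the curvature angle of a
    bent cylindrical shaft (such as the penile shaft in hypospadias/chordee
    assessment) from 2D photographs or binary masks. Provides a synthetic
    phantom generator with analytic ground truth, deterministic shaft
    localization and cropping, threshold-and-morphology segmentation,
    medial-axis extraction with three-zone partitioning into distal,
    curvature and proximal regions, four-landmark (distal/proximal mid-axis
    dot) derivation, vector-based angle computation, and the full evaluation
    suite (mAP, accuracy/IoU/DSC, normalized mean error, mean absolute
    error). Tabular results are returned as tibbles with broom-style tidiers
    and ggplot2 plotting methods.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
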