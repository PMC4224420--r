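Package: camdce
Title: Multi-Tissue Compartment Deconvolution of Dynamic Contrast-Enhanced Imaging by Convex Analysis of Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised deconvolution of dynamic contrast-enhanced imaging
    series from heterogeneous tumors. Normalized pixel time-courses are
    clustered by affinity propagation with expectation-maximization
    refinement, the compartment time-activity curves are identified as the
    vertices of the scatter simplex by an exhaustive convex-hull-to-data
    search, the number of vascular compartments is detected by a minimum
    description length criterion, and tissue-specific flux rate constants,
    relative volume transfer constants and per-pixel transfer-constant maps
    are estimated by Toeplitz-based deconvolution and non-negative least
    squares. Includes a synthetic study generator emulating rim/core tumour
    vascular heterogeneity with designated pure-volume pixel regions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    MASS,
    pracma,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
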