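Package: jswmorph
Title: Three-Dimensional Joint Space Morphometry for HR-pQCT Joint Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies metacarpophalangeal (MCP) joint space morphology from
    high-resolution peripheral quantitative computed tomography (HR-pQCT)
    volumes. Segments the two articulating bones, builds periosteal and
    joint-space masks by 3D morphological processing, computes a local
    joint-space-width (JSW) map by maximal-inscribed-sphere local thickness
    over an exact Euclidean distance transform, and summarizes it into six
    morphometric parameters (JSV, JSW, JSW.SD, JSW.MIN, JSW.MAX, JSW.AS).
    Includes synthetic joint phantoms with analytic ground truth, study-style
    inclusion rules and segmentation bookkeeping, and the matched case-control
    nonparametric statistics used in clinical joint-space studies of
    hereditary hemochromatosis arthropathy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    rlang,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
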