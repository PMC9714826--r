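Package: strokeloc
Title: Detection and Localization of Acute Ischemic Stroke on Non-Contrast CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for detecting and localizing acute
    ischemic-stroke infarcts on axial non-contrast CT slices, using
    perfusion-derived label maps as the training ground truth. Provides
    skull stripping and brain-mask extraction, rigid convex-hull
    registration of the perfusion frame onto the CT grid with
    nearest-neighbour label transfer, hand-crafted contralateral /
    local / global intensity features with a pixel-wise classifier,
    miniature encoder-decoder feature extractors with dilated
    convolutions, a two-layer convolutional ensemble fusing feature
    maps over neighbouring-slice blocks, hemisphere postprocessing,
    cell-wise evaluation metrics, a leave-one-out harness, and a
    seeded synthetic phantom generator so the whole pipeline runs
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
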