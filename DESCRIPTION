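Package: amodalgrape
Title: Amodal Detection of Occluded Grape Clusters via Occlusion Synthesis and Incoherent-Region Supervision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the complete (amodal) masks of partially
    occluded grape clusters in proximal vineyard imagery without amodal
    annotations. Implements binary-mask primitives and evaluation metrics
    (boundary IoU, amodal IoU), extraction of incoherent-region supervision
    masks arising from mask size transformations, a directional overlapping
    cover strategy for synthesizing occluded/occluder/intact training
    triples from a pool of complete instances, dual-decoder segmentation
    heads with a pixel affinity learning module, and a U-Net style mask
    completion network with a region-weighted loss plus the cross-prediction
    rule that orders occluder and occluded instances. A procedural generator
    of grape-like instance scenes makes every component testable without any
    dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    png,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
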