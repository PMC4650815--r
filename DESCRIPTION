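Package: angiomorph
Title: Cerebrovascular Morphometry for Contrast-Enhanced Micro-CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphometry of the mouse cerebral vasculature in
    Hounsfield-unit calibrated micro-CT angiograms: multiscale Hessian
    (Frangi) vesselness enhancement, hysteresis segmentation,
    topology-preserving 3D skeletonization with centerline graph extraction,
    and per-vessel measurement of diameter, arc:chord tortuosity, middle
    (Menger) curvature, Circle-of-Willis width, branch counts and a CNR-based
    visibility score, followed by a normality-gated two-group comparison
    (Kolmogorov-Smirnov gate routing to a two-sided t-test or Wilcoxon
    rank-sum test). A synthetic phantom generator emulates the acquisition
    physics (contrast dose to HU, projection count to noise, scan geometry to
    voxel size) so that every stage of the pipeline can be validated as
    parameter recovery against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
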