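Package: tubemorph
Title: 3D Nuclear Morphometry, Spatial and Cell-Cycle Analyses for Neural
    Tube Epithelial-Mesenchymal Transition Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative pipeline for characterising epithelial versus
    transformed (mesenchymal-like) states of embryonic neural tube cells in
    3D image stacks: nuclear segmentation with a size/saturation quality
    filter, moment-based ellipsoid fitting with prolate/oblate ellipticity
    and sphericity, nuclear orientation in embryo polar coordinates,
    distance-to-apical-surface and emigration quantification, DBSCAN cell
    clustering with exponential cluster-size modelling, marker-positivity
    counting with Mann-Whitney comparisons, and Dean-Jett-Fox univariate
    DNA-content cell-cycle deconvolution. A synthetic embryo-phantom
    generator (tissue geometry, rendered nuclei, image noise, depth
    attenuation, debris, DNA-content event tables) makes every stage
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
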