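Package: hsbrain
Title: Intraoperative Hyperspectral Imaging Pipeline for Brain Tumor
    Delineation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: End-to-end processing of intraoperative visible/near-infrared
    hyperspectral images of the exposed brain surface: ENVI cube input and
    output, white/dark reference reflectance calibration, a spectral
    homogenization chain, spectral-angle-mapper assisted gold-standard
    labeling, a spatial-spectral supervised stage (probabilistic support
    vector machine, first-principal-component guide image and k-nearest
    neighbor probability filtering), bisecting hierarchical K-means
    segmentation, and majority-voting fusion into a four-class "three
    maximum density" map in which tumor tissue is rendered red. A synthetic
    phantom generator emulates intraoperative scenes (class-distinct smooth
    spectral signatures, intra- and inter-subject variability, sensor noise,
    illumination gain and specular highlights) together with matching white
    and dark references, so the whole chain is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    e1071,
    jsonlite,
    methods,
    png,
    Rcpp,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'calibration.R'
    'classify.R'
    'cluster.R'
    'constants.R'
    'fusion.R'
    'hsbrain-package.R'
    'hsio.R'
    'labeling.R'
    'preprocess.R'
    'pipeline.R'
    'synth.R'
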