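Package: gliaquant
Title: Quantification of Microglia and Purkinje Cell Imaging in the Cerebellum
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cerebellar microglia and Purkinje cells from
    two-photon time-lapse and fixed-tissue confocal fluorescence images:
    preprocessing (blinding, drift correction, channel bleed-through
    subtraction, temporal PCA denoising, layer substacks), deterministic
    segmentation surrogates (threshold plus morphology binarization, soma
    detection, subcomponent classification), microglia process dynamics
    (motility index, surveillance ratio), laser-ablation injury convergence,
    Sholl ring-intersection curves with a hierarchical Bayesian change-point
    model, spatial statistics (density, nearest-neighbor spacing index,
    Purkinje cell linear frequency), and 3-D microglia-Purkinje interaction
    indices. A synthetic-data generator with full ground truth drives
    end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    rjags,
    coda,
    mgcv,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
biocViews: Software, CellBiology, Visualization, Preprocessing
RoxygenNote: 7.3.3
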