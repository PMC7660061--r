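Package: EndoEnsemble
Title: Ensemble CNN Classification of Pathological Sites in GI Endoscopy Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for triaging gastrointestinal endoscopy
    frames into frames with and without pathological sites (polyps or complex
    vascular patterns). Provides projection-profile background removal, three
    convolutional classifier architectures (VGG-, Inception- and
    DenseNet-style) with a compact built-in training engine, MAX / AVERAGE /
    majority-VOTING score fusion, patient-disjoint two-fold evaluation with
    testing-size-weighted averaging, GAR-versus-FAR ROC curves,
    gradient-weighted class activation maps, and a synthetic endoscopy-frame
    generator so that the whole pipeline is runnable and testable without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
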