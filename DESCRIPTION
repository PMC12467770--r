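Package: expressivity
Title: Neural Mutual-Information Probing of Image-Classifier Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how strongly clinically relevant attributes (demographics and
    echocardiographic dimensions) are encoded in the internal feature representations of
    image classifiers, by neural estimation of mutual information ("expressivity") via the
    Donsker-Varadhan lower bound. Includes desk-scale convolutional and transformer
    backbones with layer-wise feature taps, a synthetic cohort and radiograph-like image
    generator with closed-form ground-truth mutual information, class-balanced subset
    construction, AUROC/AUPRC evaluation with bootstrap confidence intervals, and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
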