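Package: numalign
Title: Developmental Alignment of Symbolic and Nonsymbolic Number Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates how a dorsal-visual-stream-inspired convolutional
    network acquires symbolic number semantics through a staged,
    developmentally inspired curriculum. Provides generators for
    area- and hull-controlled dot-array stimuli and distorted numeral
    glyphs, a compact four-stage (V1/V2/V3/IPS) convolutional trunk with
    swappable comparison and labeling decoders trained by backpropagation,
    the three-stage curriculum with cross-format and cross-label mapping
    conditions, behavioral analyses (accuracy, ordered pair accuracy,
    generalized and forgotten pairs), and representational analyses
    (neural representational similarity matrices, metric multidimensional
    scaling with rotational alignment to the number line, and
    symbolic/nonsymbolic alignment metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
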