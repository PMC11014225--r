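Package: breathpanel
Title: Breath VOC Chromatogram Analysis and Diagnostic Panel Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for exhaled-breath volatile organic compound
    (VOC) chromatograms from portable gas chromatography, aimed at
    case/control diagnostic panel discovery. Provides a synthetic
    micro-GC chromatogram generator (exponentially modified Gaussian
    peaks on a drifting baseline), Savitzky-Golay de-noising, asymmetric
    least-squares baseline correction, quality-control screening of
    technically inadequate runs, prominence-based peak detection and
    integration, cross-sample retention-time alignment, compound-library
    annotation, Fisher linear discriminant analysis with shrinkage,
    exhaustive leave-one-out cross-validated feature-subset search,
    principal component projections, and confusion-matrix evaluation of
    the selected biomarker panel on held-out samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal,
    pracma,
    jsonlite,
    yaml,
    data.table,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'discover.R'
    'evaluate.R'
    'io.R'
    'peaks.R'
    'simulate.R'
    'pipeline.R'
    'preprocess.R'
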