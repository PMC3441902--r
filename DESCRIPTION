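Package: imsmnf
Title: Minimum Noise Fraction Transforms for Imaging Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dimension reduction of MALDI imaging mass spectrometry data by
    the minimum noise fraction (MNF) transform. Estimates the spectrum
    covariance and a spatial noise covariance from 4-neighbour local-linear
    pseudo-residuals on the spot grid, solves the generalised eigenproblem
    to order bands by spatial signal-to-noise ratio, and supports the full
    companion pipeline: log and robust-spline baseline preprocessing,
    SNR/intensity channel pre-filtering, PCA for comparison, hierarchical
    clustering of spots in band space, continuous-mode imzML and delimited
    matrix input/output, band-image rendering, and a synthetic spot-grid
    generator with planted spatial components for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    splines,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    xml2,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'grid-model.R'
    'covariance.R'
    'transforms.R'
    'clustering.R'
    'imsmnf-package.R'
    'imzml.R'
    'preprocess.R'
    'synthetic.R'
    'pipeline.R'
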