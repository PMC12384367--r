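Package: sersquant
Title: Quantitative Chemometrics for Surface-Enhanced Raman Spectra
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying trace analytes (polycyclic aromatic
    hydrocarbons such as pyrene in edible oil) from surface-enhanced Raman
    spectra. Provides a synthetic spectrum generator with a Langmuir
    (saturating) concentration response and replicate-level multiplicative
    noise, Gaussian peak fitting, spectral-window segmentation, per-window
    principal component analysis with variance-contribution region selection,
    a small one-dimensional convolutional + dense regression network trained
    by backpropagation (PCA-BP), a partial least squares regression
    comparator, and univariate calibration with a signal-to-noise-ratio-3
    limit of detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Metabolomics, Spectrometry, Regression, DimensionReduction
RoxygenNote: 7.3.3
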