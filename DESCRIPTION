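Package: conelearn
Title: Unsupervised Discovery of Cone Spectral Classes from Response Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates retinal cone mosaics viewing hyperspectral scenes and
    implements an unsupervised algorithm that recovers, from the cone-to-cone
    response correlation matrix alone, how many longer-wavelength-sensitive
    cone classes the mosaic contains and the spectral class of every cone.
    Includes a synthetic hyperspectral scene generator with natural-image-like
    spatial and spectral correlation structure, a shiftable photopigment
    nomogram for cone spectral sensitivities, center-surround opponency,
    non-metric multidimensional scaling (SMACOF with isotonic disparities,
    STRESS1), quadratic-surface flattening of the embedding, and skew-normal
    mixture classification with Kolmogorov-Smirnov model selection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    vegan,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
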