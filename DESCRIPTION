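Package: carophen
Title: Image-Based Colorimetric Phenotyping and Carotenoid Prediction in
    Cassava Roots
Version: 0.1.0
Authors@R:
    person("Carophen", "Developers", email = "carophen@example.org",
           role = c("aut", "cre"))
Description: Tools for image-based phenotyping of cassava root pulp color
    and prediction of total carotenoid content (TCC). Converts RGB
    root-slice photographs to CIELAB colorimetric indices (L*, a*, b*,
    hue, chroma, and a 0-240 lightness index), segments roots from a blue
    background, computes TCC from spectrophotometric absorbance,
    characterizes phenotypic diversity (correlation, PCA, k-means,
    Tukey group contrasts), and benchmarks twelve regression and
    machine-learning models for TCC prediction under three
    cross-validation designs, including leave-one-cluster-out. A
    synthetic-data generator produces phenotype tables, labeled
    root-slice images, and assay records with the statistical structure
    of a biofortified cassava panel so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml,
    optparse
Config/testthat/edition: 3
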