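Package: berryshape
Title: Morphometric Phenotyping and Ordinal Shape Progression for Fruit Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end phenotyping of fruit shape from binary segmentation
    masks. Normalizes masks to a common 100 x 100 binary raster, extracts a
    dictionary of quantitative shape features (linear and geometric
    descriptors, elliptical Fourier coefficients, Procrustes pseudo-landmark
    features, eigen-image principal components, and biomass profiles),
    clusters shapes with k-means, orders the discovered clusters on an
    ordinal scale with the Principal Progression of k Clusters (PPKC)
    algorithm, selects informative features by random-forest out-of-bag
    importance, classifies shapes with linear discriminant analysis and
    support vector machines under a cross-validation protocol, and estimates
    clone-mean broad-sense heritability of both quantitative features and
    ordinal shape classes. Includes a parametric berry-shape simulator with a
    genotype x harvest x block replication structure so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    MASS,
    e1071,
    ranger,
    lme4,
    pracma,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
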