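Package: moplsda
Title: Multi-Model OPLS-DA and S-Plot Feature Selection for Three-Class
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Orthogonal partial least squares discriminant analysis
    (OPLS-DA) fitted by NIPALS with built-in orthogonal signal correction,
    S-plot covariance/correlation ranking of genes, and multi-model
    orchestration (hierarchical subtype and parallel one-versus-rest
    arrangements) for selecting marker-gene panels that separate three
    disease classes in microarray-style expression matrices. Includes
    Golub-style preprocessing (intensity clipping, variation filtering,
    log10 transform, centering), seven-fold cross-validated Q2 with
    CV-ANOVA significance, panel validation by PCA and agglomerative
    clustering with optimal cluster-to-class misclassification counting,
    a planted-marker synthetic data generator, and strict GCT/CLS/TSV
    readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
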