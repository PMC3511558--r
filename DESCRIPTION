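Package: annoqc
Title: Annotation Quality Control for Subcellular Location Pattern Collections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for automated quality control of protein subcellular
    location annotations in large immunofluorescence image collections such
    as the Human Protein Atlas. Per-cell feature vectors are classified with
    nested cross-validated support vector machines (with stepwise
    discriminant feature selection), and likely mis-annotated proteins are
    flagged by two complementary routes: a recursive label-flip
    "distillation" of the supervised classifier, and unsupervised
    hierarchical clustering with AIC model selection and two cluster-based
    mis-annotation scores. A random-sampling baseline, reannotation outcome
    tallies, reannotation rates and enrichment folds quantify the yield of
    each route. A seeded synthetic-cohort generator emulating the
    statistical structure of such collections makes every stage testable
    without image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    withr
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    tiff,
    yaml,
    optparse
Config/testthat/edition: 3
biocViews: Classification, Clustering, CellBiology, Proteomics,
    QualityControl
RoxygenNote: 7.3.3
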