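Package: delimkit
Title: Integrative Species Delimitation from DNA Barcodes and Morphology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative-taxonomy toolkit for delimiting species from
    single-locus DNA barcode data and traditional morphology. Implements
    Kimura two-parameter distance and diversity statistics on aligned
    sequences, Automatic Barcode Gap Discovery (ABGD) partitioning with a
    prior-divergence scan, maximum-likelihood fitting of the general mixed
    Yule-coalescent (GMYC) threshold model with likelihood-ratio tests and
    tree-sample conspecificity aggregation, neutrality tests (Tajima's D and
    Fu's Fs with coalescent significance), hierarchical AMOVA and Mantel
    isolation-by-distance tests, smoothed heteroscedastic discriminant
    analysis with jackknife identification for morphometric data, and a
    coalescent-based synthetic-data generator so that every stage of the
    pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    vegan,
    MASS,
    geosphere,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
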