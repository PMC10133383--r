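Package: cohesiondelim
Title: Cohesion Species Delimitation from Niche Models and Genomic Clustering
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for integrative cohesion species delimitation in
    dispersal-limited taxa. Tests ecological interchangeability with
    presence-background maximum-entropy species distribution models (AICc
    candidate-model selection), Schoener's D niche overlap, and niche
    equivalency and background-similarity randomization tests under multiple
    background-region definitions. Tests genetic exchangeability with
    replicate single-SNP-per-locus matrices, one-hot encoding, variational
    autoencoder and principal component embeddings, and quantitative
    cluster-separation verdicts. A decision engine combines both lines of
    evidence under explicit rejection-rule policies. Includes a synthetic-data
    generator (autocorrelated climate fields, Gaussian-niche occurrences,
    F-model locus alignments, morphometric trait tables) so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    grDevices,
    cluster,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
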