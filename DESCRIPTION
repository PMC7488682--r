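Package: hillbeta
Title: Hill-Number Beta Diversity, Raup-Crick Null Models and Consensus
    Count Tables for Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies beta diversity of microbial community count tables
    with Hill-based dissimilarity indices across a continuum of diversity
    orders q, decomposes diversity into alpha, gamma and beta components,
    and interprets observed dissimilarities with a generalized Raup-Crick
    null model that randomly assembles samples from a regional taxon pool.
    Also provides consensus merging of amplicon sequence variant (ASV)
    tables produced by different denoising pipelines, rarefaction,
    sequencing-depth simulation, and permutation tests (Mantel, permanova)
    on dissimilarity matrices.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
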