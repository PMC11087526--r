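Package: songlines
Title: Comparative Analysis of Musical, Linguistic and Genetic Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for asking whether musical diversity tracks
    linguistic and genetic history. Provides maximum-likelihood
    confirmatory factor analysis for latent dimensions of song style,
    hierarchical AMOVA and pairwise Phi_ST fixation indices on song-level
    distances, the Weir-Cockerham F_ST estimator for biallelic genotype
    panels, distance-class spatial autocorrelation (variograms) with
    permutation tests and bootstrap intervals, quartet delta scores of
    treelikeness, Mantel / partial Mantel tests and partial redundancy
    analysis on principal-coordinate reductions of distance matrices, and
    a synthetic-world generator (society phylogeny, geography, latent
    musical traits with tunable horizontal transmission, songs, and
    allele-frequency drift) with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
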