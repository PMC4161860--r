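Package: detoxprof
Title: Comparative Functional Profiling of Detoxification Gene Families in
    Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the abundance of detoxification-related
    protein families in shotgun metagenomes relative to the expectation from
    sequenced bacterial genomes. Parses profile-HMM search tables (HMMER3
    tblout/domtblout), applies per-profile trusted cutoffs and reciprocal
    best-profile filtering, converts per-site read counts to per-genome
    equivalents using a single-copy marker gene (rpoB), normalizes against
    genome copy-number expectations ("paralog normalization"), and provides
    the comparative layer: cross-site coefficients of variation, two-way
    hierarchical clustering, habitat/region/pollution group comparisons and
    environmental PCA. Includes a synthetic-data generator that emulates
    genome copy-number matrices, community-weighted Poisson read sampling
    and clan-level hit confusion, so the whole pipeline is testable without
    external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
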