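Package: paleohexkit
Title: Detection, Dating and Karyotype Reconstruction of Paleopolyploidy Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ancient whole-genome duplications and
    triplications from gene orders and homology hits. Chains filtered
    homology hits into collinear (syntenic) blocks, computes synonymous and
    nonsynonymous substitution rates (Ka/Ks) for anchored gene pairs by the
    Nei-Gojobori method, fits Gaussian mixture peaks to Ks distributions with
    a two-round lineage-rate correction and linear calibration dating,
    assembles a reference-anchored multigenome alignment table, quantifies
    biased subgenome fractionation (geometric loss-run model, polyploidy
    index), and reconstructs ancestral karyotypes through an algebra of
    chromosome fusion and translocation events. A seeded paleogenome
    simulator with full truth tables makes every stage testable without
    external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
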