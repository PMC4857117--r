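Package: mitofounder
Title: Mitogenome Phylogeography: Mutation-Annotated Trees, Rho Dating and
    Founder Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mitochondrial-DNA haplogroup phylogeography built
    around position-based mutation notation (rCRS/RSRS variant profiles).
    Parses and filters EMPOP-style variant tables, builds and serializes
    mutation-annotated maximum-parsimony haplotype trees, estimates clade
    coalescence ages with the rho statistic and its heuristic (Saillard)
    standard error under a purifying-selection-corrected whole-mitogenome
    clock, identifies founder clusters of sink-population lineages under
    the f1/f2 criteria with probabilistic migration-time scans on a
    200-year grid, surveys control-region databases for diagnostic
    haplogroup motifs, and simulates coalescent genealogies with known
    demographic truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
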