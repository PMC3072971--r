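Package: spiculevol
Title: Ancestral-State Reconstruction and Homoplasy Counting for Sponge
    Spicule Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood ancestral-state reconstruction of binary
    morphological characters (presence/absence of sponge spicule types)
    on a fixed molecular phylogeny under the symmetric Mk model, with
    two-tier posterior-probability confidence calling, counting of
    independent secondary losses and convergent gains on tree edges, and
    stratification of events by bathymetric habit (shallow versus
    deep-water lineages). Also provides the supporting matrix and tree
    computations such analyses report: parsimony-informativeness site
    classification, multi-marker supermatrix concatenation with
    specimen-to-species merging, Kimura 2-parameter distances, and
    Robinson-Foulds bipartition distances; plus a seeded synthetic-data
    generator (birth-death trees, Mk characters, planted loss scenarios,
    HKY+I+G alignments) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
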