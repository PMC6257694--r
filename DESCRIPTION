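Package: molgrep
Title: Functional-Group Perception and Two-Stage Chemical Structure Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained cheminformatics engine for small-molecule
    structure and reaction databases. Reads and writes MDL V2000 molfiles,
    SD files and RXN files; perceives rings (set of all rings with a
    smallest-set-of-smallest-rings fallback), Hueckel aromaticity and
    hybridization-based atom subtypes; classifies more than sixty functional
    groups into a fixed-position 256-bit descriptor viewable as eight
    unsigned 32-bit segments; computes molecular-statistics counters,
    512-bit hashed path fingerprints and dictionary fingerprints; performs
    recursive atom-by-atom substructure and exact matching with optional
    E/Z and R/S stereochemistry checks; and provides an indexed two-stage
    (descriptor pre-selection, then atom-by-atom confirmation) search layer
    for structures and reactions, including functional-group pattern queries
    in four reaction modes and Tanimoto similarity ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    ChemmineR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
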