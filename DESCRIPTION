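Package: mucha
Title: Multiple Chemical Alignment of Small-Molecule Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multiple graph alignment of small molecules encoded as
    hydrogen-suppressed KCF (KEGG Chemical Function) graphs. Finds the
    core substructure shared by all query molecules and the
    position-aware branch substructures (building blocks) shared by
    subsets of them, producing a globally consistent multi-molecule
    atom-atom mapping. The alignment is seeded by the longest common
    atom strings (simple paths distinguished by KEGG atom labels and
    distance-matrix atom identifiers), extended over neighbouring atoms
    grouped by atom species and anchored distance profiles, and
    completed by a branch stage with randomized conflict removal.
    Per-atom distance-embedded fingerprints (DECAF) score atom-atom
    similarity when several equivalent seeds exist.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
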