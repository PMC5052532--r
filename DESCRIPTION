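Package: siftr
Title: Structural Interaction Fingerprints, Pose Triage and Binding-Site
    Geometry for Protein-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-based virtual-screening post-processing
    centred on structural interaction fingerprints (SIFt): a per-residue
    9-bit encoding of protein-ligand contacts detected from heavy-atom
    geometry, Tanimoto similarity and agglomerative clustering of poses
    against reference crystal complexes, rule-based hit triage, and
    quantitative binding-site geometry (hydrogen-bond networks, chi1
    rotamer calling, steric-clash scans, grid flood-fill cavity volumes).
    Includes deterministic synthetic-fixture generators for miniature
    complexes with planted interactions and bit strings with planted
    cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
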