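Package: kinactive
Title: Classification of Active, Substrate-Binding-Competent Protein
    Kinase Conformations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Structural criteria for identifying the catalytically
    active, substrate-binding-competent conformation of typical protein
    kinase domains: spatial DFGin and dihedral BLAminus labels of the
    XDFG motif, the beta3-Lys/C-helix-Glu salt bridge, HRD backbone
    conformation, and activation-loop N- and C-terminal states required
    for substrate binding.  Includes intramolecular ipSAE confidence
    scoring of activation loops in predicted models, detection of
    substrate-bound and autophosphorylation poses across crystal
    symmetry mates, activation-loop RMSD benchmarking conventions, and a
    deterministic synthetic-fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
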