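Package: humanizeAb
Title: Antibody Humanization by Germline CDR Grafting and Weighted
    Interatomic RMSD Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An in silico antibody humanization toolkit. Locates
    Kabat-defined complementarity-determining regions (CDRs) in murine
    variable-domain sequences by conserved-anchor rules, selects
    highest-identity human germline V and J templates, grafts murine CDRs
    onto germline frameworks with optional back mutations, and enumerates
    paired VL x VH humanized candidates. Candidate structure ensembles
    (multi-model PDB or plain coordinate tables) are scored against the
    murine reference with a weighted interatomic RMSD over CDR Calpha-Calpha
    distance matrices, with per-residue weights from Shrake-Rupley
    solvent-accessible surface area (accessibility) and reference-ensemble
    fluctuation (movability). Scores are ranked and correlated with measured
    affinities (EC50 or KD) on a log scale. A synthetic ensemble and
    affinity-panel generator with known ground truth supports validation
    without molecular dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
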