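Package: condock
Title: Ligand Binding-Site Prediction from Docking Poses and Surface Conservation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts ligand binding sites on G-protein coupled receptors and
    other proteins by rescoring blind-docking poses with evolutionary surface
    conservation. For each docked pose the residues with heavy atoms within a
    distance cutoff (default 3.5 Angstrom) of the ligand define the candidate
    binding site; the mean per-residue conservation of that site multiplied by
    the pose's docking energy score gives a combined score whose most negative
    value identifies the predicted site. Conservation is imported from
    ConSurf-style 0-9 grade tables or computed from a multiple sequence
    alignment with a Jensen-Shannon divergence column scorer. Includes the
    center-of-mass distance benchmark between predicted and reference ligand
    positions, and a seeded generator of synthetic receptor/alignment/pose
    scenarios for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    ChemmineR,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
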