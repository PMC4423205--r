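Package: spiegelmer
Title: Chirality-Aware Structural Analysis of Mirror-Image RNA Aptamer Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structural and biophysical analysis of L-RNA aptamer (Spiegelmer)
    complexes with protein targets such as the chemokine CCL2. Reads and writes
    macromolecular coordinates (PDB/mmCIF), detects D/L sugar chirality, computes
    glycosidic torsions with syn/anti classification and pseudorotation-based
    sugar puckers with the endo/exo correction required for L-nucleotides,
    classifies base pairs (Watson-Crick, Hoogsteen, named noncanonical types),
    detects pseudoknots and helix handedness, characterizes protein-RNA
    interfaces (Shrake-Rupley solvent-accessible areas, hydrogen bonds, salt
    bridges, cation-pi contacts), identifies metal ions from coordination
    distances, performs Kabsch superposition and epitope substitution mapping,
    and simulates and globally fits 1:1 Langmuir surface plasmon resonance
    kinetics with mass-transport limitation. A synthetic-data module generates
    ideal A-form helices and their exact mirror images, sugar rings at
    prescribed pucker, toy complexes, ion coordination shells and noisy
    sensorgram series so that every stage is testable without downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
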