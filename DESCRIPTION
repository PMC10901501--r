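Package: poseval
Title: Physical Validity Checks for Docked Ligand Poses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Validates predicted protein-ligand binding poses for chemical
    consistency, intramolecular geometric and energetic plausibility, and
    intermolecular clashes. Checks bond lengths, angles and non-bonded
    contacts against distance-geometry bounds, ring and double-bond
    planarity, a force-field strain-energy ratio against an ensemble of
    generated conformations, and minimum-distance and volume-overlap
    criteria against the receptor and its cofactors. Also reports
    symmetry-aware heavy-atom RMSD to reference ligands, aggregates a
    per-pose validity verdict and waterfall summaries, and computes
    local-alignment sequence identity for train/test stratification.
    Includes a synthetic fixture generator producing toy complexes and
    targeted single-defect distortions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel command line tools (obabel, obenergy) for
    InChI generation and UFF force-field energies
Config/testthat/edition: 3
RoxygenNote: 7.3.3
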