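Package: plifr
Title: Protein-Ligand Interaction Fingerprinting and Assay Analysis for
    MD Trajectories
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Geometric detection of protein-ligand interactions (hydrogen
    bonds, intramolecular hydrogen bonds, salt bridges, cation-pi and
    pi-pi stacking) across multi-model PDB trajectory frames, with
    frame-occupancy statistics, heat-map matrices and RMSD traces;
    fluorescence-polarization assay mathematics including four-parameter
    logistic IC50 fitting; active/inactive score-set discrimination
    statistics; and a synthetic-data generator that plants per-channel
    interaction occupancies in toy protein-ligand complexes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
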