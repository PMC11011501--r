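Package: bindmodes
Title: Binding-Mode and Pose Analysis of Protein-Ligand MD Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyses of protein-ligand molecular dynamics trajectories
    centred on substrate recognition by membrane acyltransferases:
    per-residue ligand contact frequencies, Gromos (Daura) conformational
    clustering of ligand poses in the receptor-aligned frame,
    distance-condition binding-mode assignment with occupancies and
    transition timelines, rigid-body ligand grafting from a resolved
    homolog complex onto a predicted receptor model with a steric-clash
    audit, and a synthetic hotspot-hopping trajectory generator that
    provides ground truth for every stage. Includes minimal FASTA and
    sequence-motif utilities and readers for PDB, GRO, DCD and
    multi-model PDB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
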