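Package: hdxtraj
Title: Differential HDX-MS Analysis and MD Trajectory Dynamics for Membrane Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for the structural dynamics of ligand-coupled
    membrane transporters, combining peptide-level differential hydrogen-deuterium
    exchange mass spectrometry (HDX-MS) with molecular-dynamics trajectory
    statistics. Implements the hybrid significance test for differential deuterium
    uptake (a global threshold from the pooled replicate standard deviation
    combined with Welch's t-test), per-residue consensus mapping from overlapping
    peptides onto structure models, ligand-pocket and polar-contact annotation of
    crystal structures, a four-atom-pair geometric criterion for binding-site
    water occupancy, and side-chain heavy-atom RMSF with replica-level state
    comparison. A synthetic-data module simulates first-order hydrogen-exchange
    kinetics with per-residue protection factors and toy trajectories with known
    ground truth, so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
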