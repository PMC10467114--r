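Package: anchortraj
Title: Trajectory Analysis of GPI-Anchored Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics trajectories of
    membrane-tethered proteins: dual-cutoff protein-lipid contact booking
    with per-residue occupancy and residence times, geometric hydrogen-bond
    detection and per-residue bond counts, tilt-angle and per-residue RMSF
    flexibility profiles with NMR-ensemble comparison, and Euler-angle
    orientation landscapes built from per-frame Kabsch superposition with
    kernel-density mode detection and representative-frame retrieval.
    Includes a synthetic-trajectory generator with analytic ground truth
    (orientation mixtures, two-state Markov contact kinetics, constructed
    hydrogen-bond geometries, per-residue positional jitter) so every
    analysis stage is testable without external data, and a command-line
    interface over multi-model PDB input.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
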