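Package: sfcollapse
Title: Selectivity-Filter Collapse and Inactivation-Switch Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for potassium-channel selectivity-filter (SF)
    inactivation studied by molecular dynamics and two-electrode voltage-clamp
    electrophysiology. Builds a conductive-to-collapsed collective coordinate
    from two reference structures and projects trajectories onto it, computes
    per-atom RMSF profiles against a restraint-distance scan, detects and
    classifies intra- versus inter-subunit hydrogen bonds of a focal residue,
    measures probe-accessible side-pocket volumes on a grid, fits Boltzmann
    conductance-voltage relations and single-exponential deactivation time
    courses, and generates synthetic structures, trajectories and recordings
    with known ground truth for validation. Reads and writes fixed-column
    (multi-model) PDB.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
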