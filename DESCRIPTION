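Package: flexfit
Title: Interactive-Style Molecular Dynamics Flexible Fitting and Model Rebuilding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless environment for rebuilding macromolecular models against
    real-space density maps in the molecular dynamics flexible fitting (MDFF)
    sense. Provides flat-bottomed dihedral restraints, capped harmonic distance
    and position restraints, secondary-structure and rotamer restraint bundles,
    density maps treated as attractive potentials with tricubic interpolation,
    a spline-based register-shift planner with moving position-restraint
    targets, real-time-style backbone validation (cis/twisted peptide bonds and
    Ramachandran classification), model-versus-model change analysis, and a
    minimal checkpointed simulation engine (minimization and low-temperature
    Langevin dynamics over a simplified geometry-maintenance force field).
    Includes synthetic fixture generators (ideal peptides, Gaussian-blob maps,
    deliberate error injection) so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
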