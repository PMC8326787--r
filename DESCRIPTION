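Package: pentagate
Title: Quantitative Structural Analysis of Pentameric Ligand-Gated Ion Channel Gating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize pH-dependent gating of pentameric
    ligand-gated ion channels (pLGICs) such as the proton-gated
    prokaryotic channel GLIC from static coordinate models and molecular
    dynamics trajectory frames. Implements pore-axis estimation and
    per-residue pore radius profiles with M2 prime-notation mapping,
    hydrophobic-gate radii and pore water occupancy, rigid-body (Kabsch)
    superposition and selection-restricted RMSD, quaternary descriptors
    (extracellular-domain spread as the radius of gyration about the
    channel axis, and domain twist as the average four-centre-of-mass
    dihedral), cutoff-based electrostatic contact and sodium-coordination
    statistics with bootstrap median confidence intervals, and principal
    component analysis of M2-M3 loop conformations with kernel density
    landscapes. A synthetic C5 pentamer generator produces coordinate
    models and mock trajectories with known ground truth so every
    analysis stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    MASS,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
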