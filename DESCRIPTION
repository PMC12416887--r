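Package: voltgate
Title: Voltage-Gating Analysis of Ion-Channel Simulation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for studying voltage activation of ion channels
    from molecular-dynamics trajectories, developed around the BK (big
    potassium) channel Core-MT construct. Implements gating-charge free-energy
    decomposition by thermodynamic integration with voltage coupling factors,
    protein-reshaped electrostatic field maps (Gaussian-smeared charge density,
    periodic Poisson solve, external transmembrane potential), per-frame
    conformational, hydration and permeation metrics (charged-group
    z-displacement, helix centre-of-mass motion and tilt, backbone RMSD, pore
    radius profiles, pore-water counts, ion permeation events, conductance
    estimates), and residue-level dynamic-network coupling analysis
    (correlation-weighted contact graphs, optimal and suboptimal pathways,
    community detection, Gaussian-mixture mutual information, and current-flow
    information betweenness). Synthetic-system generators with analytic ground
    truth (elastic networks, membrane-slab charge systems, scripted pore
    trajectories) support end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
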