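Package: ammtools
Title: Pore Hydration, Free-Energy Profiles and SSME Kinetics for
    Ammonium Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for the two-lane mechanism of electrogenic
    ammonium transport through Amt/Mep/Rh-family transporters. Quantifies
    water-wire hydration in membrane-protein pores from molecular dynamics
    trajectories (per-frame water counts, chain continuity, occupancy
    fractions under a per-subunit cutoff), maps pore pathways with a
    maximal-inscribed-sphere profiler to seed umbrella-sampling windows,
    reconstructs one-dimensional potentials of mean force by the weighted
    histogram analysis method with Bayesian-bootstrap uncertainties, builds
    proton-translocation free-energy profiles from per-site pKa or free-energy
    values, and analyses solid-supported membrane electrophysiology
    transients (one-phase exponential decay fits, lipid-to-protein-ratio
    based transport-versus-binding classification, Michaelis-Menten
    kinetics). Ships seeded synthetic-data generators with known ground
    truth for every input, so the full pipeline is testable without
    external trajectory or electrophysiology downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), methods
Imports:
    stats,
    utils,
    tools,
    bio3d,
    minpack.lm,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
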