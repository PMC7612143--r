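Package: PoreHydration
Title: Pore Hydration, Hydrophobic Gating and Wetting/De-wetting Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing water behaviour in channel-like nanopores:
    probe-sphere permeation-pathway finding and pore radius profiling,
    kernel-density water density profiles along the pathway coordinate,
    Boltzmann inversion of density into free-energy-of-wetting profiles,
    barrier extraction, closed-form nanoconfinement energetics (Boltzmann
    stabilization, cylinder capacity, Onsager dipole-in-cavity), per-water
    tracking of wetting/de-wetting events, and a seeded synthetic
    pore-trajectory generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    bio3d,
    data.table,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
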