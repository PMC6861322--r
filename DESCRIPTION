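Package: trichosim
Title: Agent-Based Multiscale Metabolic Simulation of Filamentous
    Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Boyle Lab", "Reimplementation Team", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: A multiscale, multi-paradigm metabolic simulator in which
    individual cell agents on a diffusive two-dimensional ocean grid each
    solve a scalarized two-objective flux-balance problem per time step.
    Cells of two metabolic types (photoautotrophs exporting maltose and
    diazotrophs exporting beta-aspartyl arginine) are organized into
    filaments that differentiate, split, and move, while the environment
    tracks nutrient diffusion, atmospheric gas exchange via Henry's law,
    and light attenuation with depth. Ships a packaged synthetic two-cell
    type toy metabolic network, a brute-force vertex-enumeration linear
    programming oracle for testing, and a deterministic simulation driver
    with CSV logging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
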