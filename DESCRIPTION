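Package: fluxfep
Title: Stopped-Flow Flux Kinetics, Alchemical Free-Energy Estimation, and
    Lipid-Site Allosteric Modelling for Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R:
    person("fluxfep", "maintainers", email = "fluxfep@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for leaflet-specific phospholipid modulation of
    pentameric ligand-gated ion channels. Fits stretched-exponential
    fluorescence quenching traces from stopped-flow thallium flux assays and
    extracts instantaneous flux rates, activation/desensitization time
    courses, and Hill dose-response parameters. Post-processes bidirectional
    alchemical free-energy perturbation work samples with exponential (EXP)
    and Bennett acceptance ratio (BAR) estimators, statistical-inefficiency
    subsampling, and convergence diagnostics (half-split comparison,
    per-window hysteresis). Converts state-dependent lipid transformation
    free energies into relative binding constants, site-occupancy curves,
    x50 values, and conformational-stability landscapes over ternary lipid
    compositions. Includes seeded synthetic-data generators for every input
    class so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
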