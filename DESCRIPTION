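Package: nanospringr
Title: Mechanics and Topology Analysis of DNA Origami Nanosprings
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of DNA origami nanospring experiments and
    coarse-grained simulations: extensible worm-like-chain plus Hooke spring
    modelling and two-stage fitting of optical-tweezers force-extension
    curves, force-jump event segmentation with spring-constant extraction in
    entropic and enthalpic regimes, AFM height-map analysis (backbone
    tracing, curvature radius, turn counting, crossing-point uphill-slope
    chirality calls), oxDNA trajectory parsing with RMSD/RMSF and
    total-least-squares helix fitting, junction chemo-mechanical force
    estimation, and seeded synthetic-data generators emulating every input
    class so the full pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
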