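Package: holofiber
Title: Holographic Endoscopy Simulation Through Multimode-Multicore Fiber
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An in-silico model of lensless holographic endoscopy through a
    hybrid multimode-multicore optical fiber. Provides step-index LP mode
    solvers, hexagonal corelet lattices with spiral addressing, seeded
    transmission-matrix transport models for the multimode and multicore
    regimes, binary-amplitude (Lee) hologram encoding with first-order
    isolation, four-step phase-shift interferometric calibration,
    phase-conjugate focus synthesis with quality metrics, raster-scan and
    corelet-scan fluorescence imaging of synthetic phantoms, and a
    quantitative fiber mating / reconnection protocol with rotational
    alignment search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
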