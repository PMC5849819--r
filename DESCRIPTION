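Package: sdrwatch
Title: Detection of Defective Ultrasound Linear-Array Transducers from Clinical B-Mode Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic quality-assurance monitoring of ultrasound linear-array
    transducers using images stored from the clinical workflow. Selects usable
    B-mode frames from a DICOM archive, extracts and resizes the B-mode
    rectangle so that one image column corresponds to one transducer element,
    and computes Systematic Dark Region (SDR) curves from rolling stacks of
    images via a three-path detection algorithm (repeated random-subset median
    images with peak detection, full-stack median with polynomial baseline
    subtraction, and an endpoint path). The area under the SDR curve,
    normalized by the element count, is tracked over time as a scalar
    nonuniformity indicator with threshold notification. A synthetic-data
    module generates clinical-like speckle image stacks and DICOM fixtures
    with known injected defects so the whole pipeline is testable without
    clinical archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    matrixStats,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
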