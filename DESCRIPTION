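Package: batbaro
Title: Pressure Exposure of Bats Flying Near Utility-Scale Wind Turbine Blades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the transient pressure changes a bat can experience when
    flying close to an operating utility-scale wind turbine and compares them
    with mammalian barotrauma mortality thresholds. Implements a blade-element
    momentum solver for spanwise bound circulation, a Hess-Smith panel method
    for the two-dimensional pressure field around a blade section, a Vatistas
    blade-tip vortex model with the Martin core-radius correlation, Lagrangian
    tracking of bat-sized particles through the section flow field with
    pressure-time exposure metrics, and ratio comparisons against rodent
    decompression and blast-overpressure mortality data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
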