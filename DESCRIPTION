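Package: torysim
Title: Seasonal Host-Parasitoid Models for Chestnut Gall Wasp Biological
    Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the multi-year interaction between the Asian chestnut
    gall wasp (Dryocosmus kuriphilus) and its introduced parasitoid Torymus
    sinensis.  Provides a spatially homogeneous season-map model (within-year
    ordinary differential equations whose end-of-season densities seed the
    next year) and a spatially extended two-dimensional reaction-diffusion
    version on a rectangular domain with zero-flux boundaries, integrated by
    the method of lines.  Includes generators for parasitoid release
    scenarios (corner release, regular release grids, timed and periodic
    re-releases), diagnostics for suppression times, density minima,
    implantation periods, invasion-front radii and cycle periods, a YAML
    run-configuration layer, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
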