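Package: scrdens
Title: Spatial Capture-Recapture Density Estimation for Camera-Trap Surveys
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood spatial capture-recapture (SCR) with a
    half-normal detection function on a discretized state-space, including
    multi-session fitting with shared detection parameters, per-session
    density and abundance estimates with delta-method standard errors, and
    pixel-level density surfaces. Also provides nonspatial closed-population
    estimators (M0 and Chao's Mh lower bound) converted to densities through
    effective trapping areas built from the mean maximum distance moved
    (MMDM/HMMDM), readers and writers for trap-deployment and encounter
    tables, a synthetic-data generator for checkerboard camera-trap designs,
    and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
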