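Package: focalstim
Title: Closed-Loop Optimization of Epiretinal Stimulation for Focal
    Retinal Ganglion Cell Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tuning epiretinal electrical stimulation so that
    retinal ganglion cell (RGC) activity, observed through calcium
    fluorescence imaging, becomes focal and round. Provides charge-balanced
    anodic-first pulse parameterization and the standard 46-combination
    stimulus grid; delta-F/F activity maps and best-fit-ellipse shape
    descriptors (activation area, eccentricity); per-region feedforward
    neural-network surrogates trained with Levenberg-Marquardt; an
    interior-point search of the objective |A - C| + E over pulse amplitude
    and type; a five-class response-shape classifier (explicit rules and a
    small convolutional network); and a closed-loop controller that iterates
    a 5/10/15/20/46-trial schedule until a focal response is reached. A
    synthetic-retina simulator with known ground-truth response surfaces
    stands in for the in vitro preparation so the whole loop can be run and
    evaluated against a random-sampling control without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
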