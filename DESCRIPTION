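Package: chromint
Title: Chromatic Integration Analysis for Retinal Ganglion Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how retinal ganglion cells combine signals from
    UV- and green-sensitive photoreceptor channels. Generates opsin-isolating
    dichromatic stimulus ensembles (silent substitution, chromatic-integration
    contrast ladders, chromatic and contrast-reversing gratings, locally
    restricted spot stimuli, binary white noise), simulates phenomenological
    linear-nonlinear Poisson ganglion cells, and computes the standard response
    measures: peristimulus time histograms, chromatic-integration curves and
    their crossing point, chromatic and spatial nonlinearity indices, UV-green
    and On-Off indices, balance-point polarity bias, relative UV sensitivity,
    harmonic (F1/F2) analysis, direction and orientation selectivity with
    permutation tests, spike-triggered-average receptive fields, the retinal
    dorsal-ventral midline, and linear versus rectified chromatic-integration
    models applied to two-channel natural scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
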