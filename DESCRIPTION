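Package: flimphantom
Title: Characterization of Solid Fluorescence Lifetime Standards and FLIm Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating fluorescence lifetime imaging (FLIm) systems
    against solid lifetime phantoms. Provides a deterministic forward model of
    time-correlated single-photon counting (TCSPC) decay histograms under
    periodic pulsed excitation, seeded generators for instrument response
    functions, noisy decays, wide-field FLIM cubes (quadrant phantoms and bar
    resolution targets), reabsorption/re-emission cascade decays and
    photostability dose series, lifetime estimation by iterative reconvolution
    and by log-linear tail fitting with explicit fit-window rules, per-pixel
    cube fitting with lifetime-histogram summaries, and the quality-control
    statistics (coefficient of variation, fabrication repeatability,
    photostability dose metrics, relative intensity, bar-target Michelson
    contrast) used to characterize lifetime standards.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    tiff,
    yaml,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
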