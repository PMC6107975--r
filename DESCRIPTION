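Package: lightpath
Title: Spectral Modelling of Fluorescence Microscope Light Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the light path of a fluorescence microscope from plain-text
    component spectra. Given an excitation source, excitation-path filters and
    dichroics, a dye, emission-path optics, and a detector, it computes the
    transmitted fluorescence spectrum, the excitation and emission (collection)
    efficiencies, and a relative brightness score normalised to an ideal
    Alexa-488 reference. Whole dye collections can be ranked against a fixed
    filter configuration and cross-channel bleedthrough estimated as a ratio of
    brightness scores. Includes deterministic synthetic component generators
    (Gaussian dyes, box band-pass filters, sigmoidal edge dichroics, laser
    lines, flat lamps and detectors), readers and writers for a key/value
    header + CSV spectrum file dialect, JSON setup descriptions, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    pracma,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
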