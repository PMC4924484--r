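Package: crycycle
Title: Kinetic Modeling of the Plant Cryptochrome Photocycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling the three-state flavin redox photocycle of
    Arabidopsis cryptochromes (FADox, FADH radical, FADH-). Simulates the
    coupled first-order photoreduction/reoxidation kinetics, converts
    absorbance spectra to redox-state concentrations via a two-wavelength
    Beer-Lambert relation, inverts observed concentrations to forward rate
    constants with two-state and three-state algorithms, and estimates
    photoconversion cross sections and quantum yields from blue- and
    green-light dose-response series, in vitro (protein spectra) and in vivo
    (hypocotyl growth and protein degradation readouts). A synthetic-data
    generator with known ground truth supports validation and parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
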