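Package: mcfibre
Title: Statistical Elasto-Plastic Simulation of a Mineralised Collagen Fibre
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward simulation of the compressive elasto-plastic behaviour of a
    mineralised collagen fibre at the micrometre and nanometre scale. Elasticity
    of the fibril (mineral platelets in collagen) and of the fibre (fibrils in
    extrafibrillar matrix) is described by two nested shear-lag composites. Each
    fibril is represented by a rate-independent rheological element (elastic
    spring in series with two plastic sliders with linear hardening) that is
    deactivated at an ultimate plastic strain. A fibre is a parallel bundle of
    such elements with statistically distributed properties and a sigmoidal
    recruitment of fibrils caused by surface roughness. Post-processing
    utilities implement the analytic steps used with phase-contrast
    nanotomography data: refractive-index-to-density conversion (Guinier
    approximation), Gaussian/FWHM histogram analysis, fibril-diameter
    extraction from line profiles (FFT and local minima), and sigmoid fitting
    of contact-area fractions.
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
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
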