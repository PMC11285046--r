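Package: photokin
Title: Photoisomerization Quantum Yields from In Operando UV-Vis Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines forward and backward photoisomerization quantum
    yields of a two-state photoswitch from UV-vis absorbance time series
    recorded under LED irradiation. Implements the photokinetic rate
    equations for monochromatic and emission-spectrum-integrated
    excitation (including the thermal back-reaction), photon-flux
    determination from thermopile power logs (polynomial baseline
    subtraction, transmission-loss correction, inverse-variance weighted
    averaging), Levenberg-Marquardt fitting of the quantum yield pair to
    measured absorbance, power-limit uncertainty propagation, and
    replicate aggregation. Includes a synthetic-data generator with known
    ground truth so the whole pipeline is testable without instruments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
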