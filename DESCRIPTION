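Package: corflow
Title: Selective Transport of Membrane Proteins by Cortical Actomyosin Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how membrane-associated molecules couple to
    cortical actomyosin flows and for predicting when such flows can polarize
    them. Includes a stochastic simulator of diffusing, advecting,
    membrane-exchanging particles with a synthetic fluorescence-microscopy
    renderer; Crocker-Grier style spot detection and trajectory linking;
    two-pass FFT cross-correlation particle image velocimetry (PIV) of a
    cortical texture channel; a displacement-projection estimator of advection
    velocity and the cortex coupling coefficient; a 1D
    advection-diffusion-membrane-exchange PDE model of anterior-posterior
    segregation with asymmetry metrics and phase-diagram sweeps; and
    quantification of membrane concentration profiles and FRAP turnover from
    image data.
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
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
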