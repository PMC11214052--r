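Package: photokin
Title: Parallel Photocycle Kinetic Analysis of Channelrhodopsin
    Time-Resolved Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the photocycle kinetics of light-gated
    ion channels such as the anion channelrhodopsin GtACR1 from
    time-resolved difference-absorbance data and photocurrent traces.
    Provides skewed-Gaussian spectral forms on the wavenumber scale,
    first-order kinetic schemes solved by eigen-decomposition of the rate
    matrix, global multi-exponential fitting by variable projection,
    conversion of amplitude b-spectra to sequential intermediate spectra,
    non-negative spectral deconvolution into composition matrices,
    partitioning of spectral forms between conductive and nonconductive
    parallel cycles anchored to the photocurrent plateau, microscopic
    rate fitting for equilibrium and branching scheme topologies, and a
    synthetic-data generator with a wild-type-like two-cycle ground
    truth for validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    deSolve,
    knitr,
    Matrix,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
VignetteBuilder: knitr
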