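Package: speckleTransport
Title: Light Transport Property Estimation from Speckle Structured Illumination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A closed-loop simulation and analysis toolkit for measuring the
    absorption coefficient and reduced scattering coefficient of homogeneous
    turbid media from images of diffusely backscattered speckle patterns.
    Synthesizes objective speckle illumination by Fourier-optics simulation of
    a random phase screen behind a finite aperture, models photon migration in
    semi-infinite media with White Monte Carlo ray tracing, simulates the
    imaging chain (convolution with the medium impulse response, auto-exposure,
    quantization, shot and read noise, additive fixed patterns), identifies the
    medium's spatial frequency response from input and output image ensembles
    via a fixed-pattern-cancelling autocorrelation estimator, reduces it to the
    DC and AC response parameters, and inverts calibrated parameter pairs back
    to optical properties through a Monte Carlo lookup table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    jsonlite,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
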