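Package: fringeftp
Title: Structured-Light Fringe Projection Simulation and One-Shot
    Fourier-Transform Profilometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A simulate-and-reconstruct toolkit for monochromatic
    structured-light surface measurement of face-scale biological targets.
    Simulates a laser-based sinusoidal fringe projector by scalar Fresnel
    diffraction through a grating, Fourier-transform lens and spatial
    frequency filter, and by the equivalent closed-form two-beam pattern;
    renders single-shot camera frames of fringes projected on synthetic
    surfaces under a three-component reflectance model (polarized direct
    reflection, unpolarized subsurface scattering, broadband background
    illumination) with a switchable narrow bandpass filter and polarizer;
    and reconstructs surface height from one frame by Fourier-transform
    profilometry with quality-guided two-dimensional phase unwrapping,
    together with quantitative evaluation of reconstruction accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
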