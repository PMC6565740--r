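Package: helixcdi
Title: Coherent Diffractive Imaging of Helical Filaments from Serial XFEL Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering two-dimensional projection images of helical
    biological polymers (microtubules) from serial X-ray free-electron laser
    fiber-diffraction snapshots. Provides parametric microtubule stand-ins
    (featureless tubes and sphere-helix lattices), a synthetic shot generator
    with the statistical structure of a liquid-microjet XFEL experiment
    (multi-filament incoherent sums, jet-angle jitter, Poisson noise, detector
    panel gaps), a sorting and class-averaging chain (outlier rejection,
    equatorial-angle classification, rotational alignment and merging),
    separable-Gaussian diffraction-peak fitting, iterative phase retrieval
    with tailored real-space supports, and radial/helical-parameter analysis
    (pseudo-SAXS azimuthal integration, J01 helical radius, peak-to-peak
    diameter, protofilament-number estimation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
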