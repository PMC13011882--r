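Package: halbachmri
Title: Design and Virtual Scanning of Halbach-Array Ultra-Low-Field MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for the computational design of permanent-magnet
    Halbach arrays for ultra-low-field magnetic resonance imaging and for
    virtual scanning under realistic B0 inhomogeneity.  Provides analytic
    magnetostatic field models for cuboid magnets and loop coils, genetic
    optimization of multi-ring Halbach geometries for field homogeneity,
    field-map simulation and file I/O emulating a mapping robot, passive
    (shim magnet placement) and active (shim coil current) shimming, and a
    spin-echo virtual scanner with FFT reconstruction and DICOM export that
    reproduces off-resonance geometric distortion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
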