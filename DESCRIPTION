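Package: dorwave
Title: Double-Rotation Gradient Waveforms for Multidimensional Diffusion Encoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Synthesis and analysis of double-rotation (DOR) q-vector gradient
    waveforms for tensor-valued, frequency-resolved diffusion encoding in NMR and
    MRI. Provides the DOR waveform family spanning the 2D plane of centroid
    frequency and b-tensor anisotropy; tensor-valued encoding spectra b(omega)
    with scalar summaries (b, b_delta, b_eta, centroid frequency, flow-encoding
    vector); Lorentzian diffusion spectra for planar, cylindrical and spherical
    restriction; forward signal models including the closed-form powder average
    for axisymmetric tensors; acquisition-protocol construction with synthetic
    phantom data and model fitting; and a Monte Carlo random-walk simulator that
    validates the Gaussian phase approximation against the spectral theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
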