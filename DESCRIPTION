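Package: usbeam
Title: Adaptive Minimum-Variance Beamforming for Synthetic Ultrasound Imaging
Version: 0.1.0
Authors@R: person("usbeam", "developers", email = "usbeam@example.org", role = c("aut", "cre"))
Description: A simulate-beamform-render-score toolkit for medical ultrasound
    image formation with a linear transducer array. Synthesizes RF channel
    data for point-scatterer and anechoic-cyst phantoms, applies dynamic
    receive focusing, and forms B-mode images with delay-and-sum (DAS),
    standard Capon (SCB/MVDR), recursive least squares (RLS), sequential
    regression (SER), and an improved standard Capon beamformer (ISCB) that
    combines forward-backward (Toeplitz) covariance correction, eigenvalue
    thresholding into signal and noise subspaces, and a quadratically
    constrained steering-vector correction. Image quality is scored by
    average power, center and background region power, contrast, lateral
    full-width-at-half-maximum resolution, and peak sidelobe level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
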