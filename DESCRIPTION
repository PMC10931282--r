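Package: epidmvct
Title: Local MVCT Reconstruction, Position Verification and Transit Dosimetry
    from EPID Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for megavoltage portal-image guided radiotherapy position
    verification and dose reconstruction. Simulates electronic portal imaging
    device (EPID) open-field and transmission images of a digital thorax
    phantom under programmable couch shifts, converts them to log-projections,
    reconstructs a local megavoltage CT (MVCT) with a ray-by-ray algebraic
    reconstruction technique regularized by adaptive-step total-variation
    descent (ART-TV), recovers couch-shift errors by exhaustive
    mutual-information registration against a planning CT, inverts EPID
    transmission to accelerator primary fluence with inverse-square and
    beam softening/hardening corrections, computes dose with a three-component
    pencil-beam convolution, accumulates imaging plus treatment dose, and
    compares fluence or dose maps with the global gamma index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    RNifti,
    tiff,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
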