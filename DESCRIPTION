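Package: zshimtools
Title: Automated Slice-Specific Z-Shim Selection for Spinal Cord EPI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated selection of slice-specific z-shim compensation
    gradients for gradient-echo EPI of the human spinal cord. Implements an
    EPI-reference-based method (per-slice maximum cord intensity across a
    z-shim reference scan) and a field-map-based method (slice-wise linear
    least-squares fit of the B0 field followed by rounding of the through-slice
    gradient onto the discrete shim grid, with a histogram-based robust
    variant), together with evaluation metrics for EPI time series (temporal
    SNR, coefficient of variation across slices, dVARS/refRMS outlier
    censoring, bootstrap confidence intervals, artificial volume
    reconstruction) and a physics-based synthetic-data generator (cylindrical
    cord phantom, rostro-caudally periodic through-slice field gradient,
    sinc-type through-slice dephasing, multi-echo phase images) so the whole
    pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
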