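Package: smsb0
Title: Dynamic Off-Resonance Correction for Simultaneous Multi-Slice EPI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates accelerated simultaneous multi-slice (SMS) EPI
    acquisitions of a digital brain phantom under dynamic B0 field
    perturbations, estimates per-frame zeroth- and first-order off-resonance
    from the EPI phase-correction navigators using GRAPPA shift operators
    with fractional powers, corrects the raw k-space before SMS/GRAPPA
    reconstruction, and quantifies the downstream impact on image bias,
    temporal SNR, GLM activation estimates and split-half reliability of
    task fMRI analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
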