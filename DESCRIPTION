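Package: bbbpatlak
Title: Patlak Modelling and Histogram Noise Correction for DCE-MRI
    Blood-Brain Barrier Leakage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies subtle blood-brain barrier leakage from
    dual-time-resolution dynamic contrast-enhanced MRI. Converts spoiled
    gradient-echo signal to gadolinium concentration via T1 mapping,
    estimates the voxel-wise leakage rate K_i and plasma fraction v_p
    with the Patlak linear tracer-kinetic model against a sagittal-sinus
    vascular input function, applies a histogram noise correction
    (mirroring and subtracting the negative-K_i distribution) to obtain
    mean K_i and the fractional leakage volume v_L per tissue class, and
    runs the group and plasma-VEGFA standardized-beta regression layer.
    Includes a seeded synthetic-cohort generator so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    pracma,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
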