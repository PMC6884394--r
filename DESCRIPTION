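Package: rulemvpa
Title: Time-Resolved Multivoxel Pattern Analysis of Instruction-Based Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how newly instructed stimulus-response rules are
    represented across the first few implementation trials of a task. The package
    generates bias-free trial sequences built from per-stage "atomic" randomization
    units, simulates ground-truthed task fMRI data (canonical HRF, AR(1) noise,
    block-local multivoxel identity codes), estimates single-trial responses with
    a least-squares-separate GLM (Fourier instruction model, discrete-cosine
    high-pass filter, AR(1) prewhitening), computes stage-resolved identity-specific
    pattern similarity in ROI and searchlight form with white-matter bias
    regression, and provides group inference (repeated-measures ANOVA with
    Greenhouse-Geisser correction, max-statistic sign-flip permutation FWE),
    beta-series functional connectivity contrasts, and subjective-accuracy
    behavioral scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
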