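Package: capdyn
Title: Seed-Based Co-Activation Pattern Dynamics for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-based co-activation pattern (CAP) analysis of resting-state
    fMRI time series. Provides motion scrubbing by framewise displacement,
    nuisance regression, discrete-cosine high-pass filtering and z-scoring of
    gray-matter-masked volume series; selection of high-amplitude seed frames;
    consensus clustering with PAC (proportion of ambiguously clustered pairs)
    model selection and k-means CAP extraction; reference-based assignment of
    held-out frames with a correlation-percentile threshold; per-subject state
    dynamics (entries, durations, occupancy, transition probabilities); and
    covariate-adjusted group comparison with false-discovery-rate control.
    Includes a synthetic cohort generator with planted latent-state structure
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
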