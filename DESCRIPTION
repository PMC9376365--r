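Package: alphaconn
Title: EEG Alpha Spectral Analysis and Resting-State Functional Connectivity by APOE Genotype
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven pipeline for studying apolipoprotein E (APOE)
    genotype effects on resting-state brain physiology. Computes per-channel
    1-Hz alpha subband logit relative powers and individual alpha peak
    frequency (IAPF) from multi-channel resting EEG; denoises ROI BOLD time
    series (24-parameter motion expansion, aCompCor principal components,
    framewise-displacement scrubbing, 0.01-0.1 Hz band-pass) and builds
    Fisher-z ROI-to-ROI connectivity matrices; and provides the inferential
    machinery used in such studies: mixed repeated-measures ANOVA with
    Duncan multiple-range post-hoc tests, edge-wise group contrasts with
    Benjamini-Hochberg FDR control, correlation tests, and Fisher r-to-z
    comparison of correlations. Synthetic cohort, EEG, and BOLD generators
    with full ground truth make every stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
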