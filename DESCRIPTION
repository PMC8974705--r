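Package: hdemgclean
Title: Motion-Artifact Removal for High-Density Surface EMG During Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cleaning 64-channel high-density surface
    electromyography (HD-EMG) recorded during walking and running.
    Implements three processing pipelines: plain 20 Hz high-pass
    filtering, principal component analysis (PCA) component cleaning,
    and canonical correlation analysis (CCA) component cleaning based
    on lag-1 autocorrelation, each with statistical channel screening,
    per-component spectral noise cancellation, longitudinal
    differential derivation on a 13x5 electrode grid, gait-phase
    segmentation from vertical ground reaction force, spatial RMS
    activation maps, and band-wise spectral comparisons with
    repeated-measures ANOVA and false-discovery-rate correction. A
    seeded synthetic HD-EMG and ground-reaction-force generator
    provides ground truth for validating artifact removal and signal
    preservation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
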