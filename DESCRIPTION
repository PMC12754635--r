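Package: entrainKit
Title: Frequency-Tagging Analysis of Infant Statistical Learning and
    Rhythmic Ability EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for frequency-tagging studies of infant neural
    entrainment linking statistical learning and rhythmic ability.
    Generates statistical-learning syllable streams and syncopated rhythm
    event timelines, simulates multichannel infant EEG with controlled
    phase locking, implements the preprocessing chain (mastoid
    re-referencing, bandpass and notch filtering, bad-channel
    interpolation, Artifact Blocking, interval excision, outer-ring
    removal), computes inter-trial coherence spectra and the word /
    syllable / meter / beat entrainment indices, and provides the
    Bayesian inference layer: one-sided Bayes factors for Kendall's
    tau-b under a stretched beta prior, and Bayesian model averaging for
    linear regression with Jeffreys-Zellner-Siow priors, including
    inclusion probabilities, robustness curves and collinearity checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
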