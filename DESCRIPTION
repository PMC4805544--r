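Package: vtarpe
Title: Spike-Train Analysis of Cached and Inferred Value Prediction Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse trial-aligned ventral tegmental area (VTA)
    spike trains recorded in a sensory-preconditioning task. Implements
    bin-wise ROC (auROC) normalization of firing rates against a pre-cue
    baseline, classification of neurons into phasic and sustained response
    archetypes by principal components and complete-linkage hierarchical
    clustering, waveform-based screening for putative dopamine neurons,
    and the population statistics that contrast cached-value (directly
    conditioned) with inferred-value (preconditioned) cue responses.
    Includes an inhomogeneous-Poisson synthetic-data generator that
    reproduces the three-phase task structure, and deterministic
    model-free (temporal-difference) and model-based agent simulations
    that formalize why a preconditioned cue cannot elicit a cached-value
    prediction error.
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
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
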