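Package: eegattn
Title: Spectral EEG Markers of Goal-Driven and Stimulus-Driven Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of multichannel scalp EEG for contrasting
    goal-driven (planned) and stimulus-driven (unplanned) attentional states.
    Provides a seeded synthetic-EEG study generator (1/f background,
    band-limited oscillators, shared latent sources, eye-blink artifacts),
    EDF input/output, a preprocessing chain (zero-phase FIR band-pass, notch,
    automated independent-component artifact rejection, common average
    reference, epoching), Welch band-power extraction for theta and alpha,
    surface-Laplacian current source density with spectral coherence for
    frontoparietal connectivity, normalized spectral entropy, a within-subject
    label-permutation test for unequal trial counts with Bonferroni control,
    and subject-independent cross-validated SVM classification with ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    e1071,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
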