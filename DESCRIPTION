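Package: eegaffect
Title: Arousal-Valence Decoding of Emotional Stimuli from Prefrontal EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how emotional stimuli are encoded in prefrontal
    EEG activity. Implements instantaneous arousal (beta/alpha band-power ratio
    over AF3, AF4, F3, F4) and valence (frontal alpha asymmetry, alpha power at
    F4 minus F3) estimation with zero-phase Butterworth filtering,
    stimulus-locked epoching under a randomized block stimulus protocol,
    four-class emotion decoding with a small feed-forward neural network under
    stratified k-fold cross-validation (plus a linear-kernel SVM comparison),
    per-emotion arousal-valence centroid analysis on the Thayer plane, and
    verbal-response statistics for a longitudinal two-group design
    (Shapiro-Wilk normality gate, exact Wilcoxon matched-pairs signed-rank
    test, paired across-session comparison). A synthetic-data module generates
    multichannel EEG with planted per-emotion affective structure, stimulus
    schedules, and verbal responses, so the full pipeline is testable end to
    end without access to recorded participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    signal,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
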