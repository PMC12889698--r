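Package: adaptleak
Title: Simulation and Analysis of Context-Dependent Leaky Evidence Accumulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the temporal stability of recent sensory
    experience shapes perceptual decisions, sensory-neuron adaptation, and
    pupil-linked arousal. Provides a synthetic-data generator for a switching
    random-dot motion adaptation task (two-epoch stimulus schedules, leaky
    evidence-accumulator choices, direction-tuned Poisson spike trains with
    per-presentation adaptation, and pupil traces with blinks and
    context-dependent evoked components), maximum-likelihood fitting of
    time-dependent lapse-logistic psychometric functions with trial-wise
    neural or pupil modulators, spike-train rate estimation with ROC
    discriminability and adaptation metrics, a five-step pupillometry
    preprocessing pipeline with sliding-window regression, and session-level
    model comparison via Tjur's coefficient of discrimination against
    shuffled nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
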