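Package: surgflow
Title: Multimodal Surgical Workflow Assessment for Laparoscopic
    Cholecystectomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for speech-and-video surgical workflow analysis of
    laparoscopic cholecystectomy. Synchronizes per-frame video phase
    probabilities with interval-based speech phase probabilities and fuses
    them with a weighted late-fusion rule (equal modality weight by default,
    frame weights split within each speech fragment, pseudo-phase
    elimination, video-only fallback). Converts fused timelines into phase
    segments and timewise assessment metrics (total and per-phase time,
    occupancy, occurrence counts and durations), estimates the embedded
    Markov chain of phase transitions, and compares a trainee's workflow
    against a reference workflow with the first-order Wasserstein distance.
    Includes frame-wise evaluation metrics against ground truth, a seeded
    synthetic procedure and classifier simulator for end-to-end testing
    without recordings or trained models, CSV/JSON readers and writers for
    all stream, workflow and report formats, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
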