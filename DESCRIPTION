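Package: p300battery
Title: P300b-Based Cognitive Assessment Battery: Protocols, Simulation and
    Cluster-Mass Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a motor-independent cognitive assessment battery built
    on the auditory P300b event-related potential. Generates the three-task
    protocol (auditory attention oddball streams, a Sternberg-style working
    memory span task, and a grammatical reasoning task with its sentence
    solver), forward-simulates 16-channel EEG with a posterior-maximal P300b
    and a behavioral agent of configurable accuracy, preprocesses recordings
    (band-pass filtering, epoching, baseline correction, artifact rejection),
    bins epochs into task-specific correct/incorrect conditions, performs
    spatiotemporal cluster-mass permutation tests at group and
    single-participant level, models individual performance from normalized
    ERP magnitudes, and runs Monte Carlo analyses relating testing time and
    accuracy to statistical sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal
Config/testthat/edition: 3
RoxygenNote: 7.3.3
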