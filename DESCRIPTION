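Package: mudecode
Title: Motor-Unit-Based Decoding of Joint Torque from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating isometric joint torque from surface
    electromyography (EMG) and decomposed motor-unit (MU) spike trains.
    Implements three linear decoders: EMG amplitude (aEMG), neural drive
    (ND, multiple regression on MU firing rates) and MUDrive, which
    convolves MU spike trains with modeled force twitches whose pool
    parameters are fitted by a genetic algorithm. Includes
    spike-triggered-averaging validation of decomposed units,
    Monte-Carlo one-at-a-time parameter sensitivity analysis with an
    SD-convergence stopping rule, refinement of the optimization to the
    most sensitive parameters, two-fold cross-validated evaluation with
    paired post-hoc statistics, and a synthetic motor-unit-pool trial
    generator (recruitment-ordered pools, rate coding with ISI jitter,
    EMG by MUAP superposition, torque by twitch superposition) that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
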