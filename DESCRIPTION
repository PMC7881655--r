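Package: myotrainr
Title: Myoelectric Prosthesis Control with Serious-Game Training Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete, hardware-free pipeline for machine-learning myoelectric
    prosthesis control and for the training instruments built around it. Provides
    Hudgins time-domain feature extraction from eight-channel surface EMG with
    sliding 128 ms windows, a seeded feed-forward neural-network regressor
    (32-50-25 tanh architecture, Adam, early stopping) mapping features to seven
    movement strengths, conversion of those strengths into a four-element signed
    command vector with grip/open conflict resolution and a four-tap moving-average
    post-filter, the trapezoidal-reference EMG recording procedure and Motion Test
    protocols, headless deterministic engines for the MyoBox and Prosthesis Gripper
    serious games, EMG pattern separability and consistency metrics (WD, IDNN,
    IDAN) with spider-plot RMS profiles, and a seedable synthetic surface-EMG
    generator used as the test bed for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
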