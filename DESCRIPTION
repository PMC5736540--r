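Package: erdswitch
Title: Beta-Band ERD Brain-Switch Simulation and Detection for Prosthesis Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating, detecting and evaluating an EEG-based
    brain switch driven by beta-band event-related desynchronization (ERD)
    over sensorimotor cortex. Includes a synthetic EEG generator with known
    ERD ground truth, deterministic preprocessing (re-referencing, bandpass
    filtering, small-Laplacian spatial filtering, epoching), Welch band-power
    and time-frequency ERD mapping with data-driven reactive-band selection,
    a shrinkage-regularized linear discriminant intent detector with
    dwell/refractory threshold logic, and a prosthetic knee-lock state
    machine for closed-loop evaluation of self-paced switch performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
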