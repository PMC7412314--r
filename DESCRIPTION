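Package: etqrs
Title: Real-Time QRS Detection with Exponential Transform and
    PD-Controlled Adaptive Thresholding
Version: 0.1.0
Authors@R:
    person("ECG Tools", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A five-stage real-time QRS-complex detector for single-lead
    electrocardiograms: Hamming-window FIR band-pass filtering, first-order
    forward differencing, an exponential nonlinear transform with moving-window
    accumulation, sliding-window extreme-point detection, and a
    proportional-derivative (PD) controlled adaptive threshold with tall-T-wave
    rejection.  Includes readers for WFDB and CSV records and beat annotations,
    beat-matching evaluation (sensitivity, positive predictivity, accuracy),
    and a seeded synthetic annotated-ECG generator so the whole pipeline is
    testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
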