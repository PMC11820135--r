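Package: mibci
Title: Motor-Imagery EEG Decoding and Closed-Loop Pneumatic Glove Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete motor-imagery (MI) brain-computer-interface stack for a
    soft rehabilitation glove: protocol-faithful synthetic EEG generation,
    annotated recording I/O (CSV and EDF+), zero-phase bandpass and notch
    filtering, phase cropping and sliding-window epoching with leakage-safe
    trial-level splits, FFT band-power featurization, a transformer encoder
    classifier trained with focal loss, a brute-force-verifiable evaluation
    suite (F1, Cohen's Kappa, accuracy, AUC, ROC), and a discrete-time
    pneumatic pressure controller with a simulated plant. Human subjects and
    physical hardware are replaced by the synthetic generator and the plant
    simulator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
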