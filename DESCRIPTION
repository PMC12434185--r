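Package: acgtools
Title: Acoustic Cardiography: Systolic Time Intervals and Preeclampsia Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for acoustic cardiography (synchronized ECG-phonocardiogram)
    analysis. Simulates beat-structured ECG-PCG recordings with exact
    ground-truth event times; preprocesses signals (zero-phase bandpass,
    Daubechies-6 wavelet-packet denoising) with device-style quality control
    (signal quality index, motion and baseline-drift rejection, gain
    calibration); detects QRS complexes and S1/S2 heart sounds via MFCC
    features and dynamic time warping; computes per-beat and per-recording
    systolic time intervals (LVET, EMAT, LVST) and second-heart-sound
    amplitude indices (Q2S2Max); and fits a diagnostic-model layer for
    preeclampsia risk (group tests, forward-stepwise logistic regression,
    ROC with Youden cutoff, DeLong confidence intervals and tests) on real
    or simulated cohorts.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
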