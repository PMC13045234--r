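Package: throatspeech
Title: Synthetic Throat-Vibration Corpora and Dual-Head Emotional Speech
    Recognition
Version: 0.1.0
Authors@R:
    person("Throatspeech", "Developers", email = "throatspeech@noreply.dev",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing throat-vibration recordings
    captured by a wearable laryngeal strain-sensor patch. Provides a
    calibrated synthetic-corpus generator with emotion-dependent prosody
    (speech rate, pausing, amplitude, spectral band structure), an emulation
    of the sensor telemetry chain (voltage-divider readout, 12-bit ADC at
    4 ksps, IMA ADPCM compression), speech-signal preprocessing
    (pre-emphasis, endpoint detection, framing), a 40 x 128 MFCC
    delta-feature stack, a hybrid convolutional-recurrent-attention network
    with joint emotion and sentence classification heads, and
    leave-one-subject-out cross-validation with confusion-matrix reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rhdf5,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
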