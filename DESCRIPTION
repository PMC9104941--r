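Package: radarvitals
Title: FMCW Radar Vital-Sign Extraction and Arrhythmia Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates millimetre-wave FMCW radar returns from a breathing,
    beating chest; extracts heart and breathing rates from slow-time phase
    via range FFT, phase unwrapping, cascaded biquad band-pass filters,
    motion denoising and adaptive peak rejection; reconstructs QRS-like
    heartbeat trains as truncated Fourier series of symmetric triangular
    pulses; computes RR-interval heart-rate-variability features; trains a
    small sigmoid multilayer perceptron with the Levenberg-Marquardt
    algorithm for arrhythmia screening; and provides descriptive and
    agreement statistics for validating rate estimates against a reference
    device.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
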